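# edmforecast

Interpretable, model-free forecasting of univariate time series by
empirical dynamic modeling (EDM), with distributional "shaded forecast
area" output. The package is aimed at analysts — epidemiologists watching
weekly mortality or case counts, ecologists with population series — who
want forecasts they can take apart: every forecast here is an explicit,
inspectable combination of moments in the past when the system behaved
the way it is behaving now.

## The method

For a series `y[1..T]`, the state at time `t` is the delay vector of its
`E` most recent values, `v_t = [y(t-E+1), ..., y(t)]`. From a forecast
origin the method finds the `n` past delay vectors nearest (Euclidean) to
the current one — the *nearest dynamic neighbors* — weights each by

    w_i = exp(-θ · d_i / d̄)

(`d̄` = mean neighbor distance; `θ = 0` gives equal weights), and reads
off each neighbor's future `z_i = [y(t_i+1), ..., y(t_i+tp)]`. The
simplex point forecast at horizon step `r` is the normalized weighted
mean `Σ w_i z_i,r / Σ w_i`.

Because a weighted mean can fall between genuinely distinct futures, the
package also builds a distributional forecast: at each horizon step it
sums one Gaussian kernel per neighbor, centered at `z_i,r`, with height
`w_i / n` and width `α = sd(y) · kw` (defined as the interval over which
the kernel exceeds a small edge density `c = 1e-4`). The summed kernel
function lies in `[0, 1]` by construction and is drawn as an opacity
gradient — the shaded forecast area. Two clusters of plausible futures
appear as two dark bands instead of one misleading middle line. A
normalized version of the same mixture is scored by CRPS in the
rolling-origin evaluator, against last-value and seasonal-naive
benchmarks.

## Worked example

```r
library(edmforecast)

series <- gen_seasonal(synth_spec(seed = 2026))   # 468 weeks, winter peaks
hp <- edm_hyperparams(E = 5, n = 7, tp = 8, theta = 1)

ns <- find_neighbors(series, hp)
ns
#> <edm_neighbors> origin t=468, 7 neighbors (7 enabled), d_bar=1579
#>   t_i      d_i       w_i enabled
#> 1 211 1312.005 0.4356551    TRUE
#> 2 109 1382.481 0.4166377    TRUE
#> 3   8 1397.246 0.4127601    TRUE
#> 4 110 1655.706 0.3504373    TRUE
#> 5 313 1677.839 0.3455593    TRUE
#> 6 364 1804.258 0.3189716    TRUE
#> 7  60 1823.518 0.3151045    TRUE
```

The seven moments in the past most similar to the last five weeks sit at
weeks 8–364 — mostly the same ascending phase of earlier winters. Each
neighbor's weight decays with its distance to the current state. The
point forecast is their weighted continuation:

```r
simplex_forecast(ns)
#> <edm_forecast> origin t=468, horizon 8
#>       +1       +2       +3       +4       +5       +6       +7       +8
#> 59474.78 59875.98 60601.92 60790.89 60703.02 60832.25 61005.70 61276.01
```

about 59.5k–61.3k deaths/week over the next two months, climbing toward
the seasonal peak. An analyst who distrusts a neighbor (say week 110, a
second vector from the same winter as week 109) can disable it, exactly
like right-clicking it in a dashboard, and everything reweights:

```r
simplex_forecast(set_neighbor_enabled(ns, 110, FALSE))
#>       +1       +2       +3       +4       +5       +6       +7       +8
#> 59500.24 59622.76 60390.29 60745.10 60551.15 60928.35 60914.42 61325.75
```

The distributional forecast and the four-panel dashboard (series +
gradient area, offset neighbors, phase space, distance bars):

```r
kp <- kernel_params(series, hp)
dens <- density_grid(ns, kp)
render_dashboard(series, ns, simplex_forecast(ns), dens,
                 path = "dashboard.png")
```

And an honest look at accuracy, replaying the final third of the series
as forecast origins:

```r
rolling_origin_evaluate(series, edm_hyperparams(E = 5, n = 7, tp = 4),
                        period = 52)
#> <edm_evaluation> 153 origins, horizon 4
#>           method metric mean_over_horizon
#> 1    edm_density   crps          728.2572
#> 2    edm_simplex    mae          996.3620
#> 3     naive_last    mae         1088.4172
#> 4 seasonal_naive    mae         1107.8335
```

The simplex point forecast beats both naive benchmarks on this seasonal
exemplar (MAE ≈ 996 vs 1088 and 1108 deaths/week over horizons 1–4), and
the CRPS of the shaded-area density is lower still — a sharper summary
than any point forecast.

## Command line

A thin CLI wraps the same functions (installed under `exec/`):

```sh
edmforecast simulate --out series.csv --seed 7
edmforecast forecast --input series.csv --tp 8 --out-point point.csv \
    --out-neighbors neighbors.csv --out-plot dashboard.png
edmforecast evaluate --input series.csv --period 52 --tp 4 --out-csv report.csv
```

`--disable 110,211` drops neighbors by time index; exports are
deterministic functions of the flags.

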