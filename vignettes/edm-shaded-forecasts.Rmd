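---
title: "Simplex forecasting with shaded forecast areas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplex forecasting with shaded forecast areas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmforecast)
```

## The forecasting model

`edmforecast` implements empirical dynamic modeling (EDM) for univariate,
evenly spaced series — a model-free approach that asks a simple question:
*when in the past did the system behave most like it is behaving right
now, and what happened next?*

Given observations $y_1, \dots, y_T$, the state at time $t$ is the delay
vector of the $E$ most recent values,

$$v_t = [y_{t-E+1}, \dots, y_t],$$

so the series is embedded into an $E$-dimensional reconstructed state
space. To forecast from an origin $t^\*$, the method finds the $n$ delay
vectors with the smallest Euclidean distance $d_i$ to $v_{t^\*}$ — the
*nearest dynamic neighbors* — and retrieves each neighbor's future vector
$z_i = [y_{t_i+1}, \dots, y_{t_i+tp}]$. Each neighbor is weighted by how
closely it resembles the current dynamics,

$$w_i = e^{-\theta\, d_i / \bar d},$$

with $\bar d$ the mean neighbor distance; $\theta = 0$ weights all
neighbors equally at 1. The simplex point forecast at horizon step $r$ is
the normalized weighted mean of the neighbors' futures,

$$\hat y_{t^\*+r} = \frac{\sum_i w_i\, z_{i,r}}{\sum_i w_i},$$

a convex combination, so every forecast lies inside the range of its
neighbors' futures.

Point forecasts discard information: when the neighbors' futures split
into distinct groups (say, one group of past analogues where a winter
mortality peak kept climbing and another where it had already turned),
the weighted mean falls *between* the groups and describes neither. The
*shaded forecast area* keeps that structure. At each horizon step $r$, a
Gaussian kernel is centered on each neighbor's future value:

$$K_{i,r}(v) = s\, w_i\, f\!\left(\frac{v - z_{i,r}}{\alpha q}\right),
\qquad K_r(v) = \sum_i K_{i,r}(v),$$

where $f$ is the standard normal density. The summed function $K_r$ is
drawn as a vertical opacity gradient per horizon step; two separated
clusters of futures show up as two dark bands.

### The kernel constants

Three constants pin the kernels to an interpretable scale:

* $s = 1/(f(0)\, n)$ makes the *sum of all $n$ kernel peaks equal 1* when
  every weight is 1, so $K_r$ maps directly onto an opacity in $[0, 1]$
  (the linear opacity map is the identity, clamped).
* $\alpha$ is the kernel *width in data units*, defined as the interval
  over which the kernel stays above a small edge density $c$
  (default $10^{-4}$). The default is $\alpha = \sigma \cdot kw$, with
  $\sigma$ the sample standard deviation of the series and $kw$ a user
  multiplier, so $kw = 1$ gives a width on the natural scale of the data.
  $\sigma$ is one of the genuinely open choices here; the standard
  deviation was chosen because it is the only scale-free, trend-robust
  single number available without further assumptions, and an explicit
  `alpha` override is provided (it is also required for constant series,
  which have no spread).
* $q$ converts that width definition into a kernel standard deviation
  $\alpha q$. Requiring $f\!\left(\tfrac{1}{2q}\right) = c$ gives the
  closed form
  $$q = \frac{1}{2\sqrt{-2\ln(c\sqrt{2\pi})}} \approx 0.12278
  \ \text{at}\ c = 10^{-4},$$
  the unique value for which $\{v : K_{i,r}(v)/ (s w_i) \ge c\}$ has
  length exactly $\alpha$.

For scoring (not drawing), `predictive_pdf()` divides $K_r$ by its exact
analytic integral $s\, \alpha q \sum_i w_i$, yielding a proper mixture
density that integrates to 1.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `E` | values per delay vector | 5 | enough to disambiguate position and slope on seasonal data without starving the neighbor pool |
| `n` | neighbors kept | 10 | a dashboard-sized set; fewer are returned (with a warning) on short series |
| `tp` | horizon, steps | 8 | two months of weekly data |
| `theta` | weight decay exponent | 1 | distance-proportional decay; 0 = equal weights |
| `kw` | relative kernel width | 1 | kernels one series-sd wide |
| `c` | kernel edge density | 1e-4 | an arbitrary low cutoff defining the width |
| `grid_points` | density grid resolution | 256 | smooth gradients at negligible cost |
| `phase_lag` | lag of the phase-space view | 1 | the classic lag plot |

`E`, `n` and `theta` defaults are pragmatic conventions, not estimates;
on real data they should be explored interactively (the tool is built for
exactly that kind of exploration, and deliberately does not auto-tune).

## Neighbor eligibility and lookahead safety

A candidate neighbor at time $t_i$ is eligible only if $t_i \ne t^\*$ and
$t_i + tp \le t^\*$: its whole future vector must be observed at or
before the forecast origin. This is stricter than merely excluding the
query vector, and it is what makes mid-series forecasting (and the
rolling-origin evaluation) honest — no value after the origin can leak
into a forecast through a neighbor's future. No additional temporal
exclusion window is applied: delay vectors overlapping the query window
remain eligible, which is appropriate for an exploratory tool where the
nearest analogues may legitimately be recent. Ties in distance are broken
toward the earlier time index, making results fully deterministic; note
that on an exactly periodic series this selects the *earliest* repeats
among the zero-distance candidates.

Disabling a neighbor (the programmatic analogue of right-clicking one in
an interactive dashboard) removes it from $\bar d$, the weights, the
point forecast, the shaded area and the exports; $\bar d$ and all weights
are recomputed over the enabled subset. The height normalizer $s$ keeps
the *configured* $n$, so disabling neighbors dims the forecast area
rather than silently renormalizing it.

## Degenerate inputs and numerical choices

* **All enabled distances zero** (exact repeats): $w_i = e^{-\theta d_i/\bar d}$
  becomes $0/0$; the implementation takes the equal-distance limit and
  sets all enabled weights to 1, so noiseless periodic series are
  forecast exactly.
* **Constant series**: no kernel width can be derived ($\sigma = 0$);
  `kernel_params()` demands an explicit `alpha`. In the evaluator, a
  constant training history makes the predictive law a point mass at the
  simplex forecast, and its CRPS reduces to the absolute error (hence a
  constant series scores exactly zero).
* **Density grids** span $[\min_i z_{i,r} - \alpha,\ \max_i z_{i,r} + \alpha]$:
  each kernel falls below the edge density $c$ within $\pm\alpha/2$ of
  its center, so this range covers all kernels with margin.
* **CRPS** is computed as
  $\int_{-\infty}^{obs} F^2\,dv + \int_{obs}^{\infty} (1-F)^2\,dv$ with the
  observation inserted as a grid node, which resolves the indicator step
  exactly; the pdf grid extends $6\alpha q$ beyond the outermost kernel
  and is padded further when the observation falls outside it.
* **Seasonal-naive benchmark**: forecasts step $r$ with
  $y_{t^\*+r-\text{period}}$ and therefore requires $tp \le$ period —
  otherwise some "forecast" values would postdate the origin.

## The rolling-origin evaluation

`rolling_origin_evaluate()` replays history: by default every eligible
step in the final third of the series becomes a forecast origin, so about
two thirds of the data always remain as history. Point forecasts
(simplex, last-value naive, seasonal naive) are scored by mean absolute
error per horizon step; the kernel predictive density is scored by CRPS,
with the kernel width derived from data up to the origin only. This
mirrors the design of a benchmark comparison for such a tool — it is a
harness for *this* package's methods against basic reference forecasts,
not a reproduction of any external benchmark's numbers.

Two calibration facts are worth knowing when reading its output. On the
chaotic logistic map (r = 3.9), the simplex forecast's horizon-1 MAE is
roughly 1% of the persistence benchmark's — delay embedding genuinely
reconstructs deterministic nonlinear dynamics. On pure white noise the
simplex/persistence MAE ratio concentrates near 0.75, *not* 1: averaging
many neighbors' futures approximates the series mean, whose expected
absolute error is $1/\sqrt{2}$ of persistence's (persistence doubles the
noise variance). That advantage is mean reversion, not dynamic skill,
and the white-noise test asserts the ratio stays in a band around this
expectation rather than claiming skill.

## What the synthetic generator does and does not emulate

`gen_seasonal()` produces the package's default exemplar: a weekly
all-cause-mortality-like count series,

$$y_t = \text{base} + \text{trend}\cdot t +
A_{\text{cycle}}\sin(2\pi t/\text{period}) + \varepsilon_t,$$

with per-cycle amplitudes $A_{\text{cycle}}$ jittered so some "flu
seasons" peak much higher than others, Gaussian observation noise, and an
optional sustained level shift (`shock_at`) that moves the series into a
new region of phase space, as a pandemic did to real mortality data.
Defaults — 468 weeks, period 52, base 55000, amplitude 5000 with 20%
per-cycle jitter, drift +10/week, noise sd 600 — are chosen to be
realistic for weekly national all-cause death counts in order of
magnitude and seasonal structure.

It deliberately does **not** emulate: asymmetric (sharp-peaked) epidemic
waveforms, holiday reporting artifacts, heteroscedastic counting noise,
or autocorrelated measurement error. Tests passing on this generator
therefore demonstrate the *mechanics* of the method — embedding, neighbor
selection, weighting, kernel summation, scoring — under realistic scale
and seasonality, not forecasting performance on real surveillance data.
`gen_logistic_map()` complements it with the canonical chaotic system
where EDM's skill is sharpest.

## Problem sizes

The shipped tests and the results script use series of 40–2000 points,
200 randomized neighbor-search cases against an exhaustive brute-force
oracle, 100 randomized kernel configurations, and a 400-point logistic
map with roughly 130 rolling origins; these sizes give the randomized
checks enough cases to be meaningful while keeping a full run fast on a
single CPU.

## Known limitations

* Univariate only; multivariate embedding and local-linear (S-map)
  variants are out of scope, as is automatic hyperparameter selection.
* EDM needs a well-populated state space near the query: strongly
  trending series push the current state into empty territory where
  "nearest" neighbors are not meaningfully similar (detrend first).
* The kernel width is global per run — one $\alpha$ for all horizon
  steps and neighbors; no per-step adaptive bandwidths.
* The reader accepts only evenly spaced, complete series; resampling and
  gap-filling are upstream concerns, and dates in labels are carried but
  never parsed.
* Rendering is static; hover/brush interactivity of a browser dashboard
  is represented by function arguments (`current_t`, neighbor disabling)
  rather than reproduced.
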