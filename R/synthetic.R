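# run code under a temporary RNG state so generators are pure in their seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification for the seasonal synthetic series generator
#'
#' Describes a mortality-like weekly count series: a base level with a mild
#' upward trend, an annual sinusoidal cycle whose peak height varies from
#' year to year (some flu seasons are much deadlier than others), Gaussian
#' observation noise, and an optional sustained level shift emulating a
#' pandemic-style regime change that moves the series into a new region of
#' phase space.
#'
#' Defaults emulate weekly all-cause mortality counts: about nine years of
#' weekly data (`length = 468`, `period = 52`), a base level of 55000
#' deaths/week, seasonal amplitude 5000 with 20% per-cycle jitter, a drift
#' of +10 deaths/week per week, and observation noise with sd 600.
#'
#' @param length number of observations `T`.
#' @param period seasonal period in steps (>= 2).
#' @param base base level, data units.
#' @param amplitude seasonal amplitude, data units.
#' @param amplitude_jitter sd of the per-cycle multiplicative amplitude
#'   jitter (0 disables it).
#' @param trend linear drift per step.
#' @param noise_sd observation noise sd (0 disables it).
#' @param shock_at optional 1-based index at which a sustained level shift
#'   begins; `NULL` for none.
#' @param shock_size magnitude of the level shift, data units.
#' @param seed integer random seed; output is a pure function of the spec.
#' @return An object of class `synth_spec`.
#' @seealso [gen_seasonal()]
#' @export
synth_spec <- function(length = 468L, period = 52L, base = 55000,
                       amplitude = 5000, amplitude_jitter = 0.2,
                       trend = 10, noise_sd = 600,
                       shock_at = NULL, shock_size = 8000, seed = 1L) {
  length <- as.integer(length)
  period <- as.integer(period)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (period < 2L) stop("period must be >= 2", call. = FALSE)
  if (amplitude_jitter < 0 || noise_sd < 0) {
    stop("amplitude_jitter and noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.null(shock_at)) {
    shock_at <- as.integer(shock_at)
    if (shock_at < 1L || shock_at > length) {
      stop("shock_at must lie within 1..length", call. = FALSE)
    }
  }
  structure(list(length = length, period = period, base = base,
                 amplitude = amplitude, amplitude_jitter = amplitude_jitter,
                 trend = trend, noise_sd = noise_sd, shock_at = shock_at,
                 shock_size = shock_size, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a seasonal, mortality-like synthetic series
#'
#' `y_t = base + trend * t + A_cycle * sin(2 * pi * t / period) + eps_t`,
#' where `A_cycle = amplitude * (1 + jitter_cycle)` is redrawn once per
#' seasonal cycle (`jitter_cycle ~ N(0, amplitude_jitter)`, floored so the
#' amplitude never goes negative) and `eps_t ~ N(0, noise_sd)`. If
#' `shock_at` is set, `shock_size` is added to every observation from that
#' index onward — a sustained regime shift.
#'
#' @param spec a [synth_spec()].
#' @return An [edm_series()] with ISO-week-style labels.
#' @examples
#' gen_seasonal(synth_spec(length = 104, period = 52, seed = 7))
#' @export
gen_seasonal <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    t <- seq_len(spec$length)
    cycle <- (t - 1L) %/% spec$period + 1L
    n_cycles <- max(cycle)
    amp_mult <- pmax(0, 1 + stats::rnorm(n_cycles, 0, spec$amplitude_jitter))
    y <- spec$base + spec$trend * t +
      spec$amplitude * amp_mult[cycle] * sin(2 * pi * t / spec$period) +
      stats::rnorm(spec$length, 0, spec$noise_sd)
    if (!is.null(spec$shock_at)) {
      idx <- t >= spec$shock_at
      y[idx] <- y[idx] + spec$shock_size
    }
    labels <- sprintf("%04d-W%02d", 2014L + (t - 1L) %/% spec$period,
                      (t - 1L) %% spec$period + 1L)
    edm_series(y, labels)
  })
}

#' Generate a logistic-map trajectory
#'
#' The logistic map `x[t+1] = r * x[t] * (1 - x[t])` is the canonical
#' deterministic nonlinear system; near `r = 3.9` it is chaotic, which
#' makes it a sharp test bed for state-space forecasting.
#'
#' @param length number of iterates to return (>= 1).
#' @param r_param growth parameter, in (0, 4].
#' @param x0 initial condition, strictly inside (0, 1).
#' @return An [edm_series()] of the trajectory starting at `x0`.
#' @export
gen_logistic_map <- function(length, r_param = 3.9, x0 = 0.2) {
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (!is.numeric(r_param) || r_param <= 0 || r_param > 4) {
    stop("r_param must lie in (0, 4]", call. = FALSE)
  }
  if (!is.numeric(x0) || x0 <= 0 || x0 >= 1) {
    stop("x0 must lie strictly inside (0, 1)", call. = FALSE)
  }
  x <- numeric(length)
  x[1L] <- x0
  if (length > 1L) {
    for (t in seq_len(length - 1L)) {
      x[t + 1L] <- r_param * x[t] * (1 - x[t])
    }
  }
  edm_series(x)
}
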