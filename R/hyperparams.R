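#' Forecasting hyperparameters
#'
#' Bundles the tunable settings of the simplex/kernel forecasting method:
#'
#' * `E` — embedding dimension, the number of consecutive values per delay
#'   vector.
#' * `n` — number of nearest dynamic neighbors retained.
#' * `tp` — forecast horizon, in series steps.
#' * `theta` — weighting exponent: neighbor weight is
#'   `exp(-theta * d_i / d_bar)`; `theta = 0` weights all neighbors equally
#'   at 1.
#' * `kw` — relative kernel width multiplier for the shaded forecast area;
#'   the kernel width in data units is `alpha = sigma * kw` with `sigma` the
#'   sample standard deviation of the series.
#' * `c` — kernel edge density: `alpha` is defined as the width of the
#'   standard normal density at height `c` (default `1e-4`, an arbitrary
#'   low value).
#' * `grid_points` — resolution of each horizon step's density grid.
#' * `phase_lag` — lag used by the phase-space view.
#'
#' @param E embedding dimension, integer >= 1.
#' @param n neighbor count, integer >= 1.
#' @param tp forecast horizon in steps, integer >= 1.
#' @param theta weighting exponent, real >= 0.
#' @param kw relative kernel width, real > 0.
#' @param c kernel edge density, real in (0, dnorm(0)).
#' @param grid_points density grid resolution, integer >= 2.
#' @param phase_lag phase-space lag, integer >= 1.
#' @return An object of class `edm_hyperparams`.
#' @examples
#' edm_hyperparams(E = 3, n = 5, tp = 4)
#' @export
edm_hyperparams <- function(E = 5L, n = 10L, tp = 8L, theta = 1,
                            kw = 1, c = 1e-4, grid_points = 256L,
                            phase_lag = 1L) {
  check_count <- function(x, name, min) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
        x < min || x != round(x)) {
      stop(sprintf("%s must be a single integer >= %d", name, min),
           call. = FALSE)
    }
    as.integer(x)
  }
  E <- check_count(E, "E", 1L)
  n <- check_count(n, "n", 1L)
  tp <- check_count(tp, "tp", 1L)
  grid_points <- check_count(grid_points, "grid_points", 2L)
  phase_lag <- check_count(phase_lag, "phase_lag", 1L)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta < 0) {
    stop("theta must be a single finite number >= 0", call. = FALSE)
  }
  if (!is.numeric(kw) || length(kw) != 1L || !is.finite(kw) || kw <= 0) {
    stop("kw must be a single finite number > 0", call. = FALSE)
  }
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c >= stats::dnorm(0)) {
    stop("c must lie strictly between 0 and dnorm(0)", call. = FALSE)
  }
  structure(list(E = E, n = n, tp = tp, theta = as.numeric(theta),
                 kw = as.numeric(kw), c = as.numeric(c),
                 grid_points = grid_points, phase_lag = phase_lag),
            class = "edm_hyperparams")
}

#' @export
print.edm_hyperparams <- function(x, ...) {
  cat(sprintf("<edm_hyperparams> E=%d n=%d tp=%d theta=%g kw=%g c=%g grid=%d lag=%d\n",
              x$E, x$n, x$tp, x$theta, x$kw, x$c, x$grid_points, x$phase_lag))
  invisible(x)
}
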