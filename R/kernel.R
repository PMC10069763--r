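#' Derive the kernel constants for the shaded forecast area
#'
#' The distributional forecast places, at each horizon step, one Gaussian
#' kernel per enabled neighbor, centered on the neighbor's future value.
#' Kernel height is proportional to the neighbor's weight and all kernels
#' share a common width `alpha` in data units. Three constants control the
#' shape:
#'
#' * `s = 1 / (dnorm(0) * n)` scales height so that the sum of all `n`
#'   kernel peaks would equal 1 if every neighbor had weight 1.
#' * `alpha = sigma_ref * kw`, with `sigma_ref` the sample standard
#'   deviation of the series, so `kw = 1` gives a kernel width on the
#'   natural scale of the data. An explicit `alpha` override is available
#'   for constant or pre-scaled series.
#' * `q = 1 / (2 * sqrt(-2 * log(c * sqrt(2*pi))))` scales width so that
#'   the interval over which the standardized kernel stays above density
#'   `c` has length exactly `alpha`: the kernel argument is
#'   `(v - center) / (alpha * q)`, and `dnorm(1 / (2*q)) == c`.
#'
#' @param series an [edm_series()] (used only for `sigma_ref`).
#' @param hp an [edm_hyperparams()] supplying `n`, `kw` and `c`.
#' @param alpha optional explicit kernel width in data units, overriding
#'   `sigma_ref * kw`.
#' @return An object of class `kernel_params`: list with `alpha`, `q`, `s`,
#'   `c`, `kw`, `sigma_ref`, `n_neighbors`.
#' @examples
#' s <- gen_logistic_map(100, 3.9, 0.4)
#' kernel_params(s, edm_hyperparams(n = 5))
#' @export
kernel_params <- function(series, hp, alpha = NULL) {
  series <- validate_series(series)
  stopifnot(inherits(hp, "edm_hyperparams"))
  sigma_ref <- stats::sd(series$values)
  if (is.null(alpha)) {
    if (!is.finite(sigma_ref) || sigma_ref == 0) {
      stop("series has no spread (sigma_ref = 0): supply an explicit `alpha` override",
           call. = FALSE)
    }
    alpha <- sigma_ref * hp$kw
  } else {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
      stop("alpha override must be a single positive number", call. = FALSE)
    }
  }
  q <- 1 / (2 * sqrt(-2 * log(hp$c * sqrt(2 * pi))))
  s <- 1 / (stats::dnorm(0) * hp$n)
  structure(list(alpha = alpha, q = q, s = s, c = hp$c, kw = hp$kw,
                 sigma_ref = sigma_ref, n_neighbors = hp$n),
            class = "kernel_params")
}

#' Evaluate one neighbor's kernel
#'
#' `s * w * dnorm((v - center) / (alpha * q))`. The peak, at
#' `v == center`, equals `w / n`; at `v == center +/- alpha/2` the density
#' has fallen to `c / dnorm(0)` times the unit-weight peak.
#'
#' @param v evaluation point(s), data units.
#' @param center the neighbor's future value at this step.
#' @param w the neighbor's weight.
#' @param kp a [kernel_params()] object.
#' @return Kernel density value(s), same length as `v`.
#' @export
kernel_value <- function(v, center, w, kp) {
  stopifnot(inherits(kp, "kernel_params"))
  kp$s * w * stats::dnorm((v - center) / (kp$alpha * kp$q))
}

#' Per-step density grids of the shaded forecast area
#'
#' For each horizon step `r` the summed kernel function
#' `K_r(v) = sum_i s * w_i * dnorm((v - z_{i,r}) / (alpha*q))` over enabled
#' neighbors is evaluated on an even grid spanning
#' `[min(z_r) - alpha, max(z_r) + alpha]`, a range that covers all kernels
#' (each falls below density `c` within `alpha/2` of its center). By
#' construction `K_r <= sum(w_i)/n <= 1`, so the value maps directly to a
#' drawing opacity; the opacity column is `K_r` clamped to `[0, 1]`.
#'
#' @param ns an `edm_neighbors` object with weights computed.
#' @param kp a [kernel_params()] object.
#' @param tp horizon (defaults to the full horizon of `ns`).
#' @param grid_points grid resolution per step.
#' @return An object of class `edm_density`: a data frame with columns
#'   `step`, `v`, `density`, `opacity` (long format, `tp * grid_points`
#'   rows), carrying `ns` origin and `kp` as attributes.
#' @export
density_grid <- function(ns, kp, tp = ns$hp$tp,
                         grid_points = ns$hp$grid_points) {
  stopifnot(inherits(ns, "edm_neighbors"), inherits(kp, "kernel_params"))
  en <- ns$enabled
  if (!any(en)) stop("all neighbors disabled", call. = FALSE)
  tp <- as.integer(tp)
  grid_points <- as.integer(grid_points)
  w <- ns$w_i[en]
  Z <- ns$Z[en, seq_len(tp), drop = FALSE]
  out <- lapply(seq_len(tp), function(r) {
    z_r <- Z[, r]
    v <- seq(min(z_r) - kp$alpha, max(z_r) + kp$alpha, length.out = grid_points)
    dens <- rowSums(vapply(seq_along(z_r),
                           function(i) kernel_value(v, z_r[i], w[i], kp),
                           numeric(grid_points)))
    data.frame(step = r, v = v, density = dens,
               opacity = pmin(pmax(dens, 0), 1))
  })
  res <- do.call(rbind, out)
  attr(res, "origin_t") <- ns$origin_t
  attr(res, "kernel_params") <- kp
  attr(res, "total_weight") <- sum(w)
  class(res) <- c("edm_density", "data.frame")
  res
}

#' Normalized predictive density for one horizon step
#'
#' The shaded-area function `K_r` is a visual density, not a probability
#' density: each kernel integrates to `s * w_i * alpha * q`, so dividing
#' `K_r` by `s * alpha * q * sum(w_i)` yields a proper mixture pdf that
#' integrates to 1 analytically. Used for CRPS scoring of the
#' distributional forecast. The grid is extended by `6 * alpha * q` beyond
#' the kernel extremes so that essentially all mass is covered.
#'
#' @param ns an `edm_neighbors` object.
#' @param kp a [kernel_params()] object.
#' @param step horizon step `r` (1-based).
#' @param grid_points grid resolution.
#' @return A data frame with columns `v` and `pdf`.
#' @export
predictive_pdf <- function(ns, kp, step, grid_points = ns$hp$grid_points) {
  stopifnot(inherits(ns, "edm_neighbors"), inherits(kp, "kernel_params"))
  en <- ns$enabled
  if (!any(en)) stop("all neighbors disabled", call. = FALSE)
  w <- ns$w_i[en]
  total_w <- sum(w)
  if (total_w <= 0) stop("zero total weight", call. = FALSE)
  z_r <- ns$Z[en, step]
  sd_k <- kp$alpha * kp$q
  v <- seq(min(z_r) - 6 * sd_k, max(z_r) + 6 * sd_k,
           length.out = as.integer(grid_points))
  dens <- rowSums(vapply(seq_along(z_r),
                         function(i) kernel_value(v, z_r[i], w[i], kp),
                         numeric(length(v))))
  data.frame(v = v, pdf = dens / (kp$s * sd_k * total_w))
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("<kernel_params> alpha=%.4g (sigma=%.4g x kw=%g), q=%.6g, s=%.6g, c=%g, n=%d\n",
              x$alpha, x$sigma_ref, x$kw, x$q, x$s, x$c, x$n_neighbors))
  invisible(x)
}
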