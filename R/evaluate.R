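#' Last-value (persistence) forecast
#'
#' The classic "no change" benchmark: every horizon step is forecast to
#' equal the value at the forecast origin. Many published forecasts fail to
#' beat it, which makes it the minimum bar for claimed skill.
#'
#' @param series an [edm_series()].
#' @param origin_t forecast origin index.
#' @param tp horizon.
#' @return An `edm_forecast`.
#' @export
naive_forecast <- function(series, origin_t, tp) {
  series <- validate_series(series)
  origin_t <- as.integer(origin_t)
  tp <- as.integer(tp)
  if (origin_t < 1L || origin_t > series$n_obs) {
    stop("origin_t out of range", call. = FALSE)
  }
  structure(list(origin_t = origin_t,
                 values = rep(series$values[origin_t], tp)),
            class = "edm_forecast")
}

#' Seasonal naive forecast
#'
#' Forecasts step `r` with the observation one full season earlier:
#' `y(origin_t + r - period)`. The standard benchmark for strongly
#' seasonal data such as weekly mortality counts.
#'
#' @param series an [edm_series()].
#' @param origin_t forecast origin index (must be >= `period`).
#' @param tp horizon; requires `tp <= period` so every forecast value is an
#'   observation at or before the origin.
#' @param period seasonal period in steps.
#' @return An `edm_forecast`.
#' @export
seasonal_naive_forecast <- function(series, origin_t, tp, period) {
  series <- validate_series(series)
  origin_t <- as.integer(origin_t)
  tp <- as.integer(tp)
  period <- as.integer(period)
  if (origin_t < period) {
    stop(sprintf("origin_t = %d precedes one full period (%d)", origin_t, period),
         call. = FALSE)
  }
  if (tp > period) {
    stop("tp must not exceed period (forecast values would postdate the origin)",
         call. = FALSE)
  }
  idx <- origin_t + seq_len(tp) - period
  structure(list(origin_t = origin_t, values = series$values[idx]),
            class = "edm_forecast")
}

#' Continuous ranked probability score by numeric integration
#'
#' Scores a predictive density against a realized observation:
#' `CRPS = integral (F(v) - 1{v >= obs})^2 dv`, with `F` the predictive
#' CDF obtained by trapezoidal integration of the pdf. Lower is better;
#' units are the data units. The grid is extended (with zero density)
#' whenever the observation falls outside it, and the observation is
#' inserted as a grid node so the indicator step is resolved exactly:
#' the score is computed as `int_{-inf}^{obs} F^2 + int_{obs}^{inf} (1-F)^2`.
#'
#' @param pdf data frame with columns `v` (ascending) and `pdf`, as from
#'   [predictive_pdf()]; should integrate to approximately 1.
#' @param observation the realized value.
#' @return A single non-negative number.
#' @export
crps_numeric <- function(pdf, observation) {
  v <- pdf$v
  f <- pdf$pdf
  if (is.unsorted(v)) {
    o <- order(v); v <- v[o]; f <- f[o]
  }
  # extend the grid so it covers the observation (zero density outside)
  span <- v[length(v)] - v[1L]
  pad <- max(span * 0.05, 1e-12)
  if (observation < v[1L]) {
    v <- c(observation - pad, observation, v)
    f <- c(0, 0, f)
  } else if (observation > v[length(v)]) {
    v <- c(v, observation, observation + pad)
    f <- c(f, 0, 0)
  } else if (!any(v == observation)) {
    pos <- findInterval(observation, v)
    fo <- stats::approx(v, f, xout = observation)$y
    v <- append(v, observation, after = pos)
    f <- append(f, fo, after = pos)
  }
  dv <- diff(v)
  cdf <- c(0, cumsum(dv * (f[-length(f)] + f[-1L]) / 2))
  io <- which(v == observation)[1L]
  below <- cdf[seq_len(io)]^2
  above <- (1 - cdf[seq.int(io, length(v))])^2
  trap <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
  trap(v[seq_len(io)], below) + trap(v[seq.int(io, length(v))], above)
}

#' Rolling-origin forecast evaluation
#'
#' Replays history: from each forecast origin, forecasts are produced using
#' only data available at that origin, then scored against the realized
#' observations. Four methods are compared per horizon step:
#'
#' * `edm_simplex` — the simplex point forecast (mean absolute error);
#' * `edm_density` — the kernel predictive density (mean CRPS), with the
#'   kernel width derived from the data up to the origin only;
#' * `naive_last` — last-value persistence (MAE);
#' * `seasonal_naive` — same week last season (MAE).
#'
#' By default the origins are every eligible step in the final third of the
#' series, so roughly two thirds of the data always remain as training
#' history.
#'
#' @param series an [edm_series()].
#' @param hp an [edm_hyperparams()].
#' @param origins integer vector of forecast origins; `NULL` for the
#'   default scheme.
#' @param period seasonal period for the seasonal-naive benchmark.
#' @return An object of class `edm_evaluation`: a data frame with columns
#'   `method`, `horizon`, `metric`, `value`, with the origins used stored
#'   in `attr(, "origins")`.
#' @export
rolling_origin_evaluate <- function(series, hp, origins = NULL, period) {
  series <- validate_series(series)
  stopifnot(inherits(hp, "edm_hyperparams"))
  period <- as.integer(period)
  n <- series$n_obs
  first_valid <- max(hp$E + hp$tp, period)
  if (is.null(origins)) {
    lo <- max(first_valid, ceiling(2 * n / 3))
    hi <- n - hp$tp
    if (lo > hi) stop("series too short for default rolling origins", call. = FALSE)
    origins <- seq.int(lo, hi)
  }
  origins <- as.integer(origins)
  if (length(origins) == 0L) stop("empty origins", call. = FALSE)
  if (any(origins < first_valid) || any(origins + hp$tp > n)) {
    stop("every origin needs E + tp steps of history, one full period, and tp future observations",
         call. = FALSE)
  }

  abs_err <- function(fc, actual) abs(fc$values - actual)
  acc <- list(edm_simplex = 0, naive_last = 0, seasonal_naive = 0,
              edm_density = 0)
  for (ot in origins) {
    actual <- series$values[ot + seq_len(hp$tp)]
    ns <- suppressWarnings(find_neighbors(series, hp, ot))
    pf <- simplex_forecast(ns)
    # kernel width must come from data available at the origin only; a
    # constant history has no natural width, so its predictive law is a
    # point mass at the simplex forecast (CRPS reduces to absolute error)
    train <- edm_series(series$values[seq_len(ot)])
    if (stats::sd(train$values) == 0) {
      crps <- abs(pf$values - actual)
    } else {
      kp <- kernel_params(train, hp)
      crps <- vapply(seq_len(hp$tp), function(r) {
        crps_numeric(predictive_pdf(ns, kp, r), actual[r])
      }, numeric(1L))
    }
    acc$edm_simplex <- acc$edm_simplex + abs_err(pf, actual)
    acc$naive_last <- acc$naive_last +
      abs_err(naive_forecast(series, ot, hp$tp), actual)
    acc$seasonal_naive <- acc$seasonal_naive +
      abs_err(seasonal_naive_forecast(series, ot, hp$tp, period), actual)
    acc$edm_density <- acc$edm_density + crps
  }
  k <- length(origins)
  res <- rbind(
    data.frame(method = "edm_simplex", horizon = seq_len(hp$tp),
               metric = "mae", value = acc$edm_simplex / k),
    data.frame(method = "edm_density", horizon = seq_len(hp$tp),
               metric = "crps", value = acc$edm_density / k),
    data.frame(method = "naive_last", horizon = seq_len(hp$tp),
               metric = "mae", value = acc$naive_last / k),
    data.frame(method = "seasonal_naive", horizon = seq_len(hp$tp),
               metric = "mae", value = acc$seasonal_naive / k)
  )
  attr(res, "origins") <- origins
  attr(res, "horizon") <- hp$tp
  class(res) <- c("edm_evaluation", "data.frame")
  res
}

#' @export
print.edm_evaluation <- function(x, ...) {
  cat(sprintf("<edm_evaluation> %d origins, horizon %d\n",
              length(attr(x, "origins")), attr(x, "horizon")))
  wide <- stats::aggregate(value ~ method + metric, data = x, FUN = mean)
  names(wide)[3L] <- "mean_over_horizon"
  print(wide, ...)
  invisible(x)
}
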