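#' Find the nearest dynamic neighbors of a forecast origin
#'
#' The heart of the simplex method. The state at `current_t` is the delay
#' vector of its `E` most recent values; this function scans all past delay
#' vectors whose `tp`-step futures are fully observed *at or before*
#' `current_t` (so no forecast can leak information from after its origin)
#' and keeps the `n` with the smallest Euclidean distance to the query.
#' Ties are broken by earlier time index, which makes the ordering fully
#' deterministic.
#'
#' Each neighbor `i` carries its time index `t_i`, its delay vector `x_i`,
#' its distance `d_i`, its future vector `z_i = [y(t_i+1), ..., y(t_i+tp)]`,
#' an `enabled` flag, and (after weighting) its weight `w_i`. Weights are
#' computed immediately with [compute_weights()] using `hp$theta`.
#'
#' @param series an [edm_series()].
#' @param hp an [edm_hyperparams()].
#' @param current_t forecast origin (1-based index into the series);
#'   defaults to the last observation.
#' @return An object of class `edm_neighbors`: a list with the query vector,
#'   a neighbor table (`t_i`, `d_i`, `w_i`, `enabled`), coordinate matrix
#'   `X` (one row per neighbor), future matrix `Z` (`n x tp`), the mean
#'   enabled distance `d_bar`, plus `origin_t` and `hp`.
#' @examples
#' s <- gen_logistic_map(120, r_param = 3.9, x0 = 0.31)
#' find_neighbors(s, edm_hyperparams(E = 3, n = 4, tp = 2))
#' @export
find_neighbors <- function(series, hp, current_t = NULL) {
  series <- validate_series(series)
  stopifnot(inherits(hp, "edm_hyperparams"))
  if (is.null(current_t)) current_t <- series$n_obs
  current_t <- as.integer(current_t)
  if (current_t < hp$E || current_t > series$n_obs) {
    stop(sprintf("no delay vector at current_t = %d (need E = %d <= current_t <= T = %d)",
                 current_t, hp$E, series$n_obs), call. = FALSE)
  }
  emb <- delay_embed(series, hp$E)
  query <- series$values[(current_t - hp$E + 1L):current_t]

  # eligibility: a candidate's future must end at or before the origin
  eligible <- emb$t != current_t & emb$t + hp$tp <= current_t
  if (!any(eligible)) {
    stop(sprintf("insufficient history for E = %d, tp = %d at current_t = %d",
                 hp$E, hp$tp, current_t), call. = FALSE)
  }
  cand_t <- emb$t[eligible]
  cand_x <- emb$coords[eligible, , drop = FALSE]
  d <- sqrt(rowSums((cand_x - matrix(query, nrow = nrow(cand_x),
                                     ncol = hp$E, byrow = TRUE))^2))
  ord <- order(d, cand_t)
  if (length(ord) < hp$n) {
    warning(sprintf("only %d eligible neighbors available (n = %d requested)",
                    length(ord), hp$n), call. = FALSE)
  }
  keep <- ord[seq_len(min(hp$n, length(ord)))]
  t_i <- cand_t[keep]
  Z <- t(vapply(t_i, function(ti) series$values[(ti + 1L):(ti + hp$tp)],
                numeric(hp$tp)))
  Z <- matrix(Z, nrow = length(t_i), ncol = hp$tp)
  ns <- structure(list(
    origin_t = current_t,
    query = query,
    t_i = t_i,
    d_i = d[keep],
    w_i = rep(NA_real_, length(keep)),
    enabled = rep(TRUE, length(keep)),
    X = cand_x[keep, , drop = FALSE],
    Z = Z,
    d_bar = NA_real_,
    hp = hp
  ), class = "edm_neighbors")
  compute_weights(ns, hp$theta)
}

#' Compute exponential distance weights for a neighbor set
#'
#' Each enabled neighbor gets weight `w_i = exp(-theta * d_i / d_bar)` where
#' `d_bar` is the mean distance over the *enabled* neighbors only. With
#' `theta = 0` every neighbor is weighted equally at 1. When all enabled
#' distances are zero (exact repeats of the query state) the ratio is taken
#' as its equal-distance limit and all enabled weights are 1. Disabled
#' neighbors receive no weight and do not enter `d_bar`.
#'
#' @param ns an `edm_neighbors` object from [find_neighbors()].
#' @param theta weighting exponent, real >= 0.
#' @return The neighbor set with `w_i` and `d_bar` updated.
#' @export
compute_weights <- function(ns, theta = ns$hp$theta) {
  stopifnot(inherits(ns, "edm_neighbors"))
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  en <- ns$enabled
  ns$w_i <- rep(NA_real_, length(ns$t_i))
  if (!any(en)) {
    ns$d_bar <- NA_real_
    return(ns)
  }
  d_bar <- mean(ns$d_i[en])
  ns$d_bar <- d_bar
  if (d_bar == 0) {
    ns$w_i[en] <- 1
  } else {
    ns$w_i[en] <- exp(-theta * ns$d_i[en] / d_bar)
  }
  ns
}

#' Enable or disable a neighbor
#'
#' The programmatic counterpart of right-clicking a neighbor in an
#' interactive dashboard: a disabled neighbor is no longer considered by
#' the point forecast, the shaded forecast area, or the exports. `d_bar`
#' and all weights are recomputed over the enabled subset.
#'
#' @param ns an `edm_neighbors` object.
#' @param t_i time index identifying the neighbor.
#' @param enabled logical flag.
#' @return The updated neighbor set.
#' @export
set_neighbor_enabled <- function(ns, t_i, enabled) {
  stopifnot(inherits(ns, "edm_neighbors"))
  pos <- match(as.integer(t_i), ns$t_i)
  if (is.na(pos)) {
    stop(sprintf("no neighbor with t_i = %d", as.integer(t_i)), call. = FALSE)
  }
  ns$enabled[pos] <- isTRUE(enabled)
  compute_weights(ns, ns$hp$theta)
}

#' Simplex point forecast
#'
#' For each horizon step `r = 1..tp` the forecast is the normalized weighted
#' mean of the enabled neighbors' future values at that step:
#' `sum(w_i * z_{i,r}) / sum(w_i)`. Being a convex combination, every
#' forecast value lies between the minimum and maximum of the enabled
#' neighbors' values at that step.
#'
#' @param ns an `edm_neighbors` object with weights computed.
#' @param tp horizon; defaults to the full horizon carried by `ns`.
#' @return An object of class `edm_forecast`: list with `origin_t` and
#'   `values` (length `tp`).
#' @export
simplex_forecast <- function(ns, tp = ns$hp$tp) {
  stopifnot(inherits(ns, "edm_neighbors"))
  tp <- as.integer(tp)
  if (tp < 1L || tp > ncol(ns$Z)) {
    stop(sprintf("tp must be in 1..%d", ncol(ns$Z)), call. = FALSE)
  }
  en <- ns$enabled
  if (!any(en)) stop("all neighbors disabled", call. = FALSE)
  w <- ns$w_i[en]
  Z <- ns$Z[en, seq_len(tp), drop = FALSE]
  vals <- as.numeric(crossprod(w, Z)) / sum(w)
  structure(list(origin_t = ns$origin_t, values = vals),
            class = "edm_forecast")
}

#' Historical mean neighbor distance
#'
#' For every eligible forecast origin strictly before `current_t`, finds
#' that origin's nearest neighbors and takes their mean distance; returns
#' the mean of those means. On the distance bar plot this is the dashed
#' reference line that contextualizes the current neighbors' distances
#' against what was typical in the past.
#'
#' @param series an [edm_series()].
#' @param hp an [edm_hyperparams()].
#' @param current_t current origin (exclusive upper bound for history).
#' @return A single non-negative number.
#' @export
mean_distance_history <- function(series, hp, current_t = NULL) {
  series <- validate_series(series)
  stopifnot(inherits(hp, "edm_hyperparams"))
  if (is.null(current_t)) current_t <- series$n_obs
  current_t <- as.integer(current_t)
  # an origin t' needs a query vector (t' >= E) and one candidate (t' >= E + tp)
  first <- hp$E + hp$tp
  if (current_t - 1L < first) {
    stop("no eligible prior forecast origin before current_t", call. = FALSE)
  }
  origins <- seq.int(first, current_t - 1L)
  means <- vapply(origins, function(tt) {
    ns <- suppressWarnings(find_neighbors(series, hp, tt))
    mean(ns$d_i)
  }, numeric(1L))
  mean(means)
}

#' @export
print.edm_neighbors <- function(x, ...) {
  cat(sprintf("<edm_neighbors> origin t=%d, %d neighbors (%d enabled), d_bar=%.4g\n",
              x$origin_t, length(x$t_i), sum(x$enabled), x$d_bar))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.edm_neighbors <- function(x, ...) {
  data.frame(t_i = x$t_i, d_i = x$d_i, w_i = x$w_i, enabled = x$enabled)
}

#' @export
print.edm_forecast <- function(x, ...) {
  cat(sprintf("<edm_forecast> origin t=%d, horizon %d\n",
              x$origin_t, length(x$values)))
  print(stats::setNames(x$values, paste0("+", seq_along(x$values))), ...)
  invisible(x)
}
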