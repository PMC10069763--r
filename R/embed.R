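#' Time-delay embedding of a series
#'
#' Represents the state of the system at each time `t` as the delay vector of
#' the `E` most recent observations `[y(t-E+1), ..., y(t)]`. The first
#' complete vector sits at `t = E`, so a series of length `T` yields
#' `T - E + 1` vectors.
#'
#' @param series an [edm_series()].
#' @param E embedding dimension, integer >= 1.
#' @return A list with `t` (integer vector of vector end-times, `E .. T`) and
#'   `coords` (matrix, one row per delay vector, `E` columns ordered oldest
#'   to newest).
#' @examples
#' delay_embed(edm_series(1:4), E = 2)
#' @export
delay_embed <- function(series, E) {
  series <- validate_series(series)
  E <- as.integer(E)
  if (E < 1L) stop("E must be >= 1", call. = FALSE)
  n <- series$n_obs
  if (n < E) {
    stop(sprintf("series too short to embed: length %d < E = %d", n, E),
         call. = FALSE)
  }
  t_idx <- seq.int(E, n)
  coords <- vapply(seq_len(E), function(k) series$values[t_idx - E + k],
                   numeric(length(t_idx)))
  coords <- matrix(coords, nrow = length(t_idx), ncol = E)
  list(t = t_idx, coords = coords)
}

#' Euclidean distance between two delay vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return The L2 distance, a single non-negative number.
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop(sprintf("dimension mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

#' Lagged coordinate pairs for the phase-space view
#'
#' Returns the scatter `(y(t - lag), y(t))` for `t = lag+1 .. T`, the
#' classic phase-space (lag) plot that reveals cycles and regime shifts —
#' e.g. a pandemic-era departure into a previously unpopulated region of
#' the reconstructed state space.
#'
#' @param series an [edm_series()].
#' @param phase_lag positive integer lag.
#' @return A data frame with columns `t`, `x` (lagged value) and `y`
#'   (current value), ordered by `t`.
#' @export
phase_space_coords <- function(series, phase_lag = 1L) {
  series <- validate_series(series)
  phase_lag <- as.integer(phase_lag)
  if (phase_lag < 1L) stop("phase_lag must be >= 1", call. = FALSE)
  if (series$n_obs <= phase_lag) {
    stop(sprintf("series length %d must exceed phase_lag %d",
                 series$n_obs, phase_lag), call. = FALSE)
  }
  t_idx <- seq.int(phase_lag + 1L, series$n_obs)
  data.frame(t = t_idx,
             x = series$values[t_idx - phase_lag],
             y = series$values[t_idx])
}
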