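#' Construct and validate an evenly spaced time series
#'
#' An `edm_series` is the package's basic data container: an ordered vector of
#' finite numeric observations `y[1..T]`, optionally accompanied by one label
#' (e.g. a date string) per observation. Spacing between observations is
#' assumed even; the container stores only ordinal positions, so any
#' resampling to enforce even spacing must happen upstream.
#'
#' @param values numeric vector of observations, ordered in time.
#' @param labels optional character vector of per-observation labels, same
#'   length as `values`.
#' @return An object of class `edm_series`: a list with elements `values`,
#'   `labels` (possibly `NULL`) and `n_obs`.
#' @examples
#' edm_series(c(1, 2, 3))
#' @export
edm_series <- function(values, labels = NULL) {
  if (length(values) == 0L) {
    stop("empty series: at least one observation is required", call. = FALSE)
  }
  if (is.list(values) || !is.numeric(values)) {
    stop("series values must be a numeric vector", call. = FALSE)
  }
  values <- as.numeric(values)
  bad <- which(!is.finite(values))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite value at index %d (all observations must be finite numbers)",
                 bad[1L]), call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(values)) {
      stop(sprintf("labels length (%d) must match values length (%d)",
                   length(labels), length(values)), call. = FALSE)
    }
  }
  structure(list(values = values, labels = labels, n_obs = length(values)),
            class = "edm_series")
}

#' Validate raw input into an `edm_series`
#'
#' Accepts either a plain numeric vector or a list of records with `label`
#' and `value` fields (the shape produced by parsing labeled JSON input),
#' rejecting missing, non-numeric or empty input with the offending index.
#'
#' @param raw numeric vector, or list of lists each holding `label` and
#'   `value` (field name `value`, or the single numeric field).
#' @return An `edm_series`.
#' @seealso [read_series()] for file input.
#' @export
validate_series <- function(raw) {
  if (inherits(raw, "edm_series")) return(raw)
  if (is.list(raw) && length(raw) > 0L && is.list(raw[[1L]])) {
    labels <- vapply(raw, function(rec) {
      if (!is.null(rec$label)) as.character(rec$label) else NA_character_
    }, character(1L))
    values <- vapply(seq_along(raw), function(i) {
      rec <- raw[[i]]
      v <- rec$value
      if (is.null(v)) {
        # fall back to the single numeric field of the record
        num <- Filter(is.numeric, rec)
        if (length(num) != 1L) {
          stop(sprintf("record at index %d has no unambiguous numeric value", i),
               call. = FALSE)
        }
        v <- num[[1L]]
      }
      if (!is.numeric(v) || length(v) != 1L) {
        stop(sprintf("non-numeric value at index %d", i), call. = FALSE)
      }
      as.numeric(v)
    }, numeric(1L))
    if (anyNA(labels)) labels <- NULL
    return(edm_series(values, labels))
  }
  edm_series(raw)
}

#' @export
print.edm_series <- function(x, ...) {
  cat(sprintf("<edm_series> %d observations", x$n_obs))
  if (!is.null(x$labels)) {
    cat(sprintf(" [%s .. %s]", x$labels[1L], x$labels[x$n_obs]))
  }
  cat("\n")
  cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.edm_series <- function(x, ...) {
  data.frame(t = seq_len(x$n_obs),
             label = if (is.null(x$labels)) NA_character_ else x$labels,
             value = x$values,
             stringsAsFactors = FALSE)
}

#' @export
length.edm_series <- function(x) x$n_obs
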