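#' Read a time series from CSV or JSON
#'
#' Accepted CSV layouts: two columns `label,value` or a single `value`
#' column; a header row is auto-detected (a non-numeric entry in the value
#' column of the first row). Accepted JSON layouts: an array of numbers, or
#' an array of objects each carrying a label field (`label` or `date`) and
#' a numeric `value` field (any unambiguous numeric field is accepted).
#' Order of appearance defines time order; timepoints are assumed evenly
#' spaced.
#'
#' @param path_or_text a file path, or the literal CSV/JSON content.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @return An [edm_series()].
#' @examples
#' read_series("[1, 2, 3]", format = "json")
#' read_series("date,deaths\n2019-01-04,55000\n2019-01-11,54000",
#'             format = "csv")
#' @export
read_series <- function(path_or_text, format = NULL) {
  is_file <- length(path_or_text) == 1L && !grepl("[\n,{\\[]", path_or_text) &&
    file.exists(path_or_text)
  if (is.null(format)) {
    if (is_file) {
      ext <- tolower(tools::file_ext(path_or_text))
      format <- if (ext == "json") "json" else "csv"
    } else {
      stop("format must be given ('csv' or 'json') when reading from text",
           call. = FALSE)
    }
  }
  format <- match.arg(format, c("csv", "json"))
  text <- if (is_file) {
    paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
  } else {
    path_or_text
  }
  if (!nzchar(trimws(text))) stop("empty file", call. = FALSE)
  if (format == "json") read_series_json(text) else read_series_csv(text)
}

read_series_csv <- function(text) {
  df <- utils::read.csv(text = text, header = FALSE, colClasses = "character",
                        strip.white = TRUE, blank.lines.skip = TRUE)
  if (nrow(df) == 0L) stop("empty file", call. = FALSE)
  if (ncol(df) > 2L) {
    stop(sprintf("expected 1 or 2 columns, found %d", ncol(df)), call. = FALSE)
  }
  value_col <- ncol(df)
  has_header <- is.na(suppressWarnings(as.numeric(df[1L, value_col]))) &&
    nzchar(df[1L, value_col])
  if (has_header) {
    if (nrow(df) == 1L) stop("no data rows after header", call. = FALSE)
    df <- df[-1L, , drop = FALSE]
  }
  raw <- df[[value_col]]
  values <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(values) | !nzchar(trimws(raw)))
  if (length(bad) > 0L) {
    row_no <- bad[1L] + if (has_header) 1L else 0L
    stop(sprintf("non-numeric or blank value in row %d: '%s'",
                 row_no, raw[bad[1L]]), call. = FALSE)
  }
  labels <- if (ncol(df) == 2L) df[[1L]] else NULL
  edm_series(values, labels)
}

read_series_json <- function(text) {
  parsed <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                     error = function(e) {
                       stop(sprintf("unparseable JSON: %s", conditionMessage(e)),
                            call. = FALSE)
                     })
  if (!is.list(parsed) || length(parsed) == 0L) {
    stop("JSON input must be a non-empty array", call. = FALSE)
  }
  if (all(vapply(parsed, is.numeric, logical(1L)))) {
    return(edm_series(unlist(parsed)))
  }
  if (!all(vapply(parsed, is.list, logical(1L)))) {
    stop("JSON array must hold numbers or {label, value} objects", call. = FALSE)
  }
  recs <- lapply(seq_along(parsed), function(i) {
    rec <- parsed[[i]]
    label <- rec$label
    if (is.null(label)) label <- rec$date
    value <- rec$value
    if (is.null(value)) {
      num <- Filter(function(x) is.numeric(x) && length(x) == 1L, rec)
      if (length(num) != 1L) {
        stop(sprintf("record %d has no unambiguous numeric value field", i),
             call. = FALSE)
      }
      value <- num[[1L]]
    }
    if (!is.numeric(value)) {
      stop(sprintf("non-numeric value in record %d", i), call. = FALSE)
    }
    list(label = if (is.null(label)) NA_character_ else as.character(label),
         value = as.numeric(value))
  })
  labels <- vapply(recs, `[[`, character(1L), "label")
  if (anyNA(labels)) labels <- NULL
  edm_series(vapply(recs, `[[`, numeric(1L), "value"), labels)
}

# full-precision number formatting for deterministic text round-trips
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a series to CSV or JSON
#'
#' Writes in the same dialects [read_series()] accepts, so fixtures and
#' exports round-trip exactly (to 17 significant digits). CSV gets a
#' `label,value` header when labels are present, otherwise a single
#' `value` column; JSON becomes an array of `{label, value}` objects or a
#' plain number array.
#'
#' @param series an [edm_series()].
#' @param path output file path.
#' @param format `"csv"` or `"json"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = NULL) {
  series <- validate_series(series)
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    if (is.null(series$labels)) {
      lines <- c("value", fmt_num(series$values))
    } else {
      lines <- c("label,value",
                 paste(series$labels, fmt_num(series$values), sep = ","))
    }
    writeLines(lines, path)
  } else {
    if (is.null(series$labels)) {
      jsonlite::write_json(series$values, path, auto_unbox = TRUE,
                           digits = I(17))
    } else {
      jsonlite::write_json(
        data.frame(label = series$labels, value = series$values),
        path, dataframe = "rows", digits = I(17))
    }
  }
  invisible(path)
}

#' Export a point forecast as CSV
#'
#' Two columns, `step` (1..tp) and `forecast`, written at full precision so
#' a read-back reproduces the forecast to float accuracy.
#'
#' @param pf an `edm_forecast`.
#' @param path output file path.
#' @param labels optional per-step labels, written as a third `label`
#'   column.
#' @return `path`, invisibly.
#' @export
write_point_forecast <- function(pf, path, labels = NULL) {
  stopifnot(inherits(pf, "edm_forecast"))
  if (length(pf$values) == 0L) stop("empty forecast", call. = FALSE)
  steps <- seq_along(pf$values)
  if (is.null(labels)) {
    lines <- c("step,forecast", paste(steps, fmt_num(pf$values), sep = ","))
  } else {
    if (length(labels) != length(pf$values)) {
      stop("labels length must match forecast length", call. = FALSE)
    }
    lines <- c("step,forecast,label",
               paste(steps, fmt_num(pf$values), labels, sep = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export enabled neighbors' futures as parallel series
#'
#' Wide CSV: one `step` column plus one column per *enabled* neighbor,
#' headed by the neighbor's time index `t_i` and holding its future vector
#' `z_i`. This export supports the workflow where each neighbor's future
#' is treated as a separate candidate trajectory and analyzed downstream.
#'
#' @param ns an `edm_neighbors` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_neighbor_series <- function(ns, path) {
  stopifnot(inherits(ns, "edm_neighbors"))
  en <- ns$enabled
  if (!any(en)) stop("all neighbors disabled", call. = FALSE)
  Z <- ns$Z[en, , drop = FALSE]
  header <- paste(c("step", paste0("t_", ns$t_i[en])), collapse = ",")
  rows <- vapply(seq_len(ncol(Z)), function(r) {
    paste(c(r, fmt_num(Z[, r])), collapse = ",")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a point-forecast CSV back
#'
#' @param path a file written by [write_point_forecast()].
#' @return An `edm_forecast` (with `origin_t = NA`).
#' @export
read_point_forecast <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("step", "forecast") %in% names(df))) {
    stop("not a point-forecast file: needs 'step' and 'forecast' columns",
         call. = FALSE)
  }
  structure(list(origin_t = NA_integer_,
                 values = df$forecast[order(df$step)]),
            class = "edm_forecast")
}
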