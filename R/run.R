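#' Configuration for a reproducible forecast run
#'
#' A run is fully determined by its configuration: input location and
#' format, hyperparameters, the forecast origin (the programmatic
#' counterpart of an interactive time slider), the list of disabled
#' neighbors (the counterpart of right-click disabling), output paths and
#' a seed. Identical configurations produce byte-identical exports.
#'
#' @param input path to (or literal text of) the input series.
#' @param format `"csv"` or `"json"` (`NULL` to guess from the extension).
#' @param hp an [edm_hyperparams()].
#' @param current_t forecast origin; `NULL` for the last observation.
#' @param disable integer vector of neighbor time indices to disable.
#' @param alpha optional explicit kernel width override.
#' @param out_point optional path for the point-forecast CSV.
#' @param out_neighbors optional path for the per-neighbor series CSV.
#' @param out_plot optional path for the dashboard image.
#' @param seed integer seed (only synthetic inputs draw random numbers,
#'   but the seed is carried so a config fully describes its run).
#' @param verbose log the neighbor table and progress to stderr?
#' @return An object of class `edm_config`.
#' @export
edm_config <- function(input, format = NULL, hp = edm_hyperparams(),
                       current_t = NULL, disable = integer(0), alpha = NULL,
                       out_point = NULL, out_neighbors = NULL,
                       out_plot = NULL, seed = 1L, verbose = TRUE) {
  stopifnot(inherits(hp, "edm_hyperparams"))
  structure(list(input = input, format = format, hp = hp,
                 current_t = current_t, disable = as.integer(disable),
                 alpha = alpha, out_point = out_point,
                 out_neighbors = out_neighbors, out_plot = out_plot,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "edm_config")
}

log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run one forecast end to end
#'
#' Reads the series, embeds it, finds and weights the nearest dynamic
#' neighbors at the configured origin, disables any listed neighbors,
#' computes the simplex point forecast and the shaded-forecast-area
#' density grids, and writes the requested exports. The neighbor table
#' (`t_i`, `d_i`, `w_i`) is logged to stderr.
#'
#' @param config an [edm_config()].
#' @return A list with `series`, `neighbors`, `forecast`, `kernel_params`
#'   and `density`, invisibly.
#' @export
run_forecast <- function(config) {
  stopifnot(inherits(config, "edm_config"))
  series <- read_series(config$input, config$format)
  hp <- config$hp
  log_msg(config$verbose, "read %d observations", series$n_obs)
  ns <- find_neighbors(series, hp, config$current_t)
  for (ti in config$disable) {
    ns <- set_neighbor_enabled(ns, ti, FALSE)
  }
  if (config$verbose) {
    tab <- as.data.frame(ns)
    message(sprintf("origin t=%d, %d/%d neighbors enabled, d_bar=%.6g",
                    ns$origin_t, sum(ns$enabled), length(ns$t_i), ns$d_bar))
    message(paste(utils::capture.output(print(tab)), collapse = "\n"))
  }
  pf <- simplex_forecast(ns)
  kp <- kernel_params(series, hp, alpha = config$alpha)
  dens <- density_grid(ns, kp)
  if (!is.null(config$out_point)) {
    write_point_forecast(pf, config$out_point)
    log_msg(config$verbose, "wrote point forecasts to %s", config$out_point)
  }
  if (!is.null(config$out_neighbors)) {
    write_neighbor_series(ns, config$out_neighbors)
    log_msg(config$verbose, "wrote neighbor series to %s", config$out_neighbors)
  }
  if (!is.null(config$out_plot)) {
    render_dashboard(series, ns, pf, dens, path = config$out_plot)
    log_msg(config$verbose, "wrote dashboard to %s", config$out_plot)
  }
  invisible(list(series = series, neighbors = ns, forecast = pf,
                 kernel_params = kp, density = dens))
}

#' Generate a synthetic fixture file
#'
#' @param spec a [synth_spec()].
#' @param path output path.
#' @param format `"csv"` or `"json"` (`NULL` to guess from the extension).
#' @return `path`, invisibly.
#' @export
run_simulate <- function(spec, path, format = NULL) {
  series <- gen_seasonal(spec)
  write_series(series, path, format)
  invisible(path)
}

#' Run a rolling-origin evaluation and write the report
#'
#' @param input path to (or literal text of) the input series.
#' @param format input format (`NULL` to guess).
#' @param hp an [edm_hyperparams()].
#' @param period seasonal period for the seasonal-naive benchmark.
#' @param origins optional explicit origins (default: final third).
#' @param out_csv,out_json optional report paths.
#' @return The `edm_evaluation` report, invisibly.
#' @export
run_evaluate <- function(input, format = NULL, hp = edm_hyperparams(),
                         period, origins = NULL,
                         out_csv = NULL, out_json = NULL) {
  series <- read_series(input, format)
  report <- rolling_origin_evaluate(series, hp, origins, period)
  if (!is.null(out_csv)) {
    utils::write.csv(as.data.frame(report), out_csv, row.names = FALSE)
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(as.data.frame(report), out_json, dataframe = "rows",
                         digits = NA)
  }
  invisible(report)
}
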