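#' Styling options for the static dashboard
#'
#' Colors are monotone ramps: neighbor markers go from light to dark red
#' with increasing weight, and the forecast area from transparent to dark
#' purple with increasing kernel density, so that darker always means more
#' strongly weighted.
#'
#' @param neighbor_low,neighbor_high endpoints of the neighbor weight ramp.
#' @param forecast_color color of the forecast gradient and dashed line.
#' @param current_color marker color for the forecast origin.
#' @param show_point_forecast draw the dashed point-forecast line?
#' @param width,height,dpi output size in inches and resolution.
#' @return An object of class `plot_style`.
#' @export
plot_style <- function(neighbor_low = "#fcae91", neighbor_high = "#99000d",
                       forecast_color = "#54278f", current_color = "#2171b5",
                       show_point_forecast = TRUE,
                       width = 11, height = 8, dpi = 150) {
  structure(list(neighbor_low = neighbor_low, neighbor_high = neighbor_high,
                 forecast_color = forecast_color, current_color = current_color,
                 show_point_forecast = isTRUE(show_point_forecast),
                 width = width, height = height, dpi = dpi),
            class = "plot_style")
}

#' Assemble the data behind the four dashboard panels
#'
#' Separates the dashboard's data from its rendering so the panel contents
#' can be inspected and tested directly. Only enabled neighbors appear in
#' any panel. Panels:
#'
#' * `chronological` — the series, the origin marker, enabled-neighbor
#'   markers at their `t_i`, the per-step forecast gradient placed at
#'   `t = origin + step`, and the point-forecast line.
#' * `offset` — the query vector and every enabled neighbor's delay vector
#'   and future, aligned on a common relative-time axis (offset 0 at the
#'   vector's most recent value), plus the gradient at offsets `1..tp`.
#' * `phase` — the lag-plot trajectory with enabled neighbors and the
#'   origin highlighted.
#' * `distances` — one bar per enabled neighbor (`d_i`, shaded by weight)
#'   and the historical mean neighbor distance as a dashed reference
#'   (`NA` when there is not enough history to compute it).
#'
#' @param series an [edm_series()].
#' @param ns the `edm_neighbors` of the forecast run.
#' @param pf the `edm_forecast` of the same run.
#' @param dens the `edm_density` grids of the same run.
#' @return A list of data frames (one per panel) plus `origin_t` and the
#'   reference distance `mean_distance`.
#' @export
dashboard_data <- function(series, ns, pf, dens) {
  series <- validate_series(series)
  stopifnot(inherits(ns, "edm_neighbors"), inherits(pf, "edm_forecast"),
            inherits(dens, "edm_density"))
  if (pf$origin_t != ns$origin_t || attr(dens, "origin_t") != ns$origin_t) {
    stop("inconsistent inputs: forecast, neighbors and density must share one origin",
         call. = FALSE)
  }
  hp <- ns$hp
  en <- which(ns$enabled)
  origin <- ns$origin_t

  neigh <- data.frame(t_i = ns$t_i[en], value = series$values[ns$t_i[en]],
                      d_i = ns$d_i[en], w_i = ns$w_i[en])
  dens_df <- as.data.frame(dens)
  dens_df$t <- origin + dens_df$step

  offset_parts <- lapply(en, function(i) {
    k <- seq.int(-hp$E + 1L, hp$tp)
    data.frame(t_i = ns$t_i[i], offset = k,
               value = series$values[ns$t_i[i] + k],
               w_i = ns$w_i[i],
               part = ifelse(k <= 0L, "history", "future"))
  })
  query_df <- data.frame(offset = seq.int(-hp$E + 1L, 0L), value = ns$query)

  phase <- phase_space_coords(series, hp$phase_lag)
  phase_neigh <- neigh[neigh$t_i > hp$phase_lag, , drop = FALSE]
  phase_neigh$x <- series$values[phase_neigh$t_i - hp$phase_lag]
  phase_neigh$y <- phase_neigh$value

  mean_dist <- tryCatch(mean_distance_history(series, hp, origin),
                        error = function(e) NA_real_)

  list(
    chronological = list(
      series = as.data.frame(series),
      origin = data.frame(t = origin, value = series$values[origin]),
      neighbors = neigh,
      gradient = dens_df,
      forecast = data.frame(t = origin + seq_along(pf$values),
                            value = pf$values)
    ),
    offset = list(
      query = query_df,
      neighbors = do.call(rbind, offset_parts),
      gradient = dens_df,
      forecast = data.frame(offset = seq_along(pf$values), value = pf$values)
    ),
    phase = list(trajectory = phase, neighbors = phase_neigh,
                 origin = if (origin > hp$phase_lag) {
                   data.frame(x = series$values[origin - hp$phase_lag],
                              y = series$values[origin])
                 } else {
                   data.frame(x = numeric(0), y = numeric(0))
                 }),
    distances = list(bars = neigh, mean_distance = mean_dist),
    origin_t = origin
  )
}

panel_chronological <- function(pd, style) {
  ch <- pd$chronological
  tile_h <- stats::ave(ch$gradient$v, ch$gradient$step,
                       FUN = function(v) diff(range(v)) / max(length(v) - 1L, 1L))
  ch$gradient$tile_height <- tile_h
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(data = ch$gradient,
                       ggplot2::aes(x = .data$t, y = .data$v,
                                    alpha = .data$opacity,
                                    height = .data$tile_height),
                       fill = style$forecast_color) +
    ggplot2::scale_alpha_identity() +
    ggplot2::geom_line(data = ch$series,
                       ggplot2::aes(x = .data$t, y = .data$value),
                       color = "grey35", linewidth = 0.4) +
    ggplot2::geom_point(data = ch$neighbors,
                        ggplot2::aes(x = .data$t_i, y = .data$value,
                                     color = .data$w_i), size = 2.2) +
    ggplot2::scale_color_gradient(low = style$neighbor_low,
                                  high = style$neighbor_high,
                                  limits = c(0, 1), name = "weight") +
    ggplot2::geom_point(data = ch$origin,
                        ggplot2::aes(x = .data$t, y = .data$value),
                        color = style$current_color, size = 3) +
    ggplot2::labs(x = "time", y = "value", title = "Series and forecast area")
  if (style$show_point_forecast) {
    p <- p + ggplot2::geom_line(data = ch$forecast,
                                ggplot2::aes(x = .data$t, y = .data$value),
                                color = style$forecast_color,
                                linetype = "dashed")
  }
  p
}

panel_offset <- function(pd, style) {
  of <- pd$offset
  tile_h <- stats::ave(of$gradient$v, of$gradient$step,
                       FUN = function(v) diff(range(v)) / max(length(v) - 1L, 1L))
  of$gradient$tile_height <- tile_h
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(data = of$gradient,
                       ggplot2::aes(x = .data$step, y = .data$v,
                                    alpha = .data$opacity,
                                    height = .data$tile_height),
                       fill = style$forecast_color) +
    ggplot2::scale_alpha_identity() +
    ggplot2::geom_line(data = of$neighbors,
                       ggplot2::aes(x = .data$offset, y = .data$value,
                                    group = .data$t_i, color = .data$w_i),
                       linewidth = 0.4) +
    ggplot2::scale_color_gradient(low = style$neighbor_low,
                                  high = style$neighbor_high,
                                  limits = c(0, 1), guide = "none") +
    ggplot2::geom_line(data = of$query,
                       ggplot2::aes(x = .data$offset, y = .data$value),
                       color = style$current_color, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "offset from vector end", y = "value",
                  title = "Offset neighbors and futures")
  if (style$show_point_forecast) {
    p <- p + ggplot2::geom_line(data = of$forecast,
                                ggplot2::aes(x = .data$offset, y = .data$value),
                                color = style$forecast_color,
                                linetype = "dashed")
  }
  p
}

panel_phase <- function(pd, style) {
  ph <- pd$phase
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = ph$trajectory,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       color = "grey65", linewidth = 0.3) +
    ggplot2::labs(x = "value (lagged)", y = "value", title = "Phase space")
  if (nrow(ph$neighbors) > 0L) {
    p <- p + ggplot2::geom_point(data = ph$neighbors,
                                 ggplot2::aes(x = .data$x, y = .data$y,
                                              color = .data$w_i), size = 2.2) +
      ggplot2::scale_color_gradient(low = style$neighbor_low,
                                    high = style$neighbor_high,
                                    limits = c(0, 1), guide = "none")
  }
  if (nrow(ph$origin) > 0L) {
    p <- p + ggplot2::geom_point(data = ph$origin,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 color = style$current_color, size = 3)
  }
  p
}

panel_distances <- function(pd, style) {
  ds <- pd$distances
  bars <- ds$bars
  bars$t_lab <- factor(bars$t_i, levels = bars$t_i[order(bars$d_i, bars$t_i)])
  p <- ggplot2::ggplot(bars,
                       ggplot2::aes(x = .data$t_lab, y = .data$d_i,
                                    fill = .data$w_i)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = style$neighbor_low,
                                 high = style$neighbor_high,
                                 limits = c(0, 1), guide = "none") +
    ggplot2::labs(x = "neighbor time index", y = "distance to query",
                  title = "Neighbor distances")
  if (is.finite(ds$mean_distance)) {
    p <- p + ggplot2::geom_hline(yintercept = ds$mean_distance,
                                 linetype = "dashed")
  }
  p
}

#' Render the four-panel forecast dashboard
#'
#' A static counterpart of an interactive EDM dashboard: (a) the
#' chronological series with weight-shaded neighbor markers, the gradient
#' forecast area and an optional dashed point-forecast line; (b) the
#' offset view overlaying the query vector and each neighbor's past and
#' future on one relative axis; (c) the phase-space lag plot with
#' neighbors highlighted; (d) the neighbor-distance bar chart with the
#' historical mean distance as a dashed reference.
#'
#' @param series,ns,pf,dens the components of one forecast run (see
#'   [dashboard_data()]).
#' @param style a [plot_style()].
#' @param path output image path (`.png`, `.svg` or `.pdf`); `NULL`
#'   returns the patchwork object without writing.
#' @return The assembled plot object, invisibly; writes `path` if given.
#' @export
render_dashboard <- function(series, ns, pf, dens, style = plot_style(),
                             path = NULL) {
  pd <- dashboard_data(series, ns, pf, dens)
  p <- patchwork::wrap_plots(
    panel_chronological(pd, style), panel_offset(pd, style),
    panel_phase(pd, style), panel_distances(pd, style),
    ncol = 2L)
  if (!is.null(path)) {
    ggplot2::ggsave(path, plot = p, width = style$width,
                    height = style$height, dpi = style$dpi)
  }
  invisible(p)
}
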