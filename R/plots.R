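#' Plot a simulation time series
#'
#' Faceted trajectories of cooperation frequency, mean linking traits and
#' mean degree over generations. For replicate bundles every replicate is
#' drawn as a thin line with the cross-replicate mean on top.
#'
#' @param object A `"coop_sim"` or `"coop_traj"` tibble.
#' @param vars Observables to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.coop_sim <- function(object,
                              vars = c("coop_freq", "mean_pr", "mean_pn",
                                       "mean_degree"), ...) {
  df <- tibble::as_tibble(object)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  long <- tidyr::pivot_longer(df, dplyr::all_of(vars),
                              names_to = "observable")
  mean_long <- long |>
    dplyr::group_by(.data$generation, .data$observable) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_long, colour = "red",
                       linewidth = 0.7) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL)
}

#' @rdname autoplot.coop_sim
#' @export
autoplot.coop_traj <- autoplot.coop_sim

#' Heatmap of a parameter-grid summary
#'
#' @param summary A tibble from [run_grid()] over two axes.
#' @param x,y Axis column names (default: the first two columns).
#' @param fill Observable to colour by.
#' @return A ggplot object.
#' @export
plot_grid_heatmap <- function(summary, x = names(summary)[1],
                              y = names(summary)[2], fill = "coop_freq") {
  ggplot2::ggplot(summary,
                  ggplot2::aes(factor(.data[[x]]), factor(.data[[y]]),
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = if (fill == "coop_freq") c(0, 1)) +
    ggplot2::labs(x = x, y = y, fill = fill)
}
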