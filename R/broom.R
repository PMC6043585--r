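#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result
#'
#' Returns the per-generation records as a plain tibble, stripped of the
#' state and configuration attributes.
#'
#' @param x A `"coop_sim"` tibble.
#' @param ... Ignored.
#' @return A tibble with one row per recorded generation.
#' @export
tidy.coop_sim <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "final_state") <- NULL
  attr(out, "config") <- NULL
  out
}

#' One-row summary of a simulation
#'
#' Trailing-window means of the recorded observables (default: last 80% of
#' recorded generations) plus the run dimensions.
#'
#' @param x A `"coop_sim"` tibble.
#' @param trailing_frac Fraction of the series to average over.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @export
glance.coop_sim <- function(x, trailing_frac = 0.8, ...) {
  cfg <- attr(x, "config")
  out <- summarize_window(tibble::as_tibble(x),
                          trailing_frac = trailing_frac)
  out$n_replicates <- NULL
  dplyr::mutate(out,
                n = cfg$n %||% NA_integer_,
                generations = max(x$generation),
                .before = 1L)
}
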