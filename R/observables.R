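#' Frequency of the cooperation allele
#'
#' @param types 0/1 allele vector.
#' @return Exact count ratio in \[0, 1\].
#' @export
cooperation_frequency <- function(types) {
  types <- check_types(types, length(types))
  mean(types)
}

#' Assortment of cooperators on the network
#'
#' The primary measure (`method = "neighbor"`) is the mean fraction of
#' cooperator neighbours among cooperators minus the same fraction among
#' defectors, both restricted to individuals with degree at least 1:
#' positive values mean cooperators interact disproportionately with other
#' cooperators, the condition that makes diluted cooperation pay. It lies
#' in \[-1, 1\] and is `NA` when either class has no connected member.
#' `method = "newman"` gives the nominal (categorical) edge assortativity
#' of the allele, recorded alongside for robustness; it is `NA` when the
#' network has no edges or all edge endpoints are of one type.
#'
#' @param net Symmetric 0/1 adjacency matrix.
#' @param types 0/1 allele vector (1 = cooperator).
#' @param method `"neighbor"` (default) or `"newman"`.
#' @return A single numeric value, possibly `NA`.
#' @examples
#' net <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 0))
#' assortment(net, c(1, 1, 0, 0)) # two segregated pairs: 1
#' @export
assortment <- function(net, types, method = c("neighbor", "newman")) {
  method <- match.arg(method)
  check_network(net)
  types <- check_types(types, nrow(net))
  d <- rowSums(net)
  if (method == "neighbor") {
    connected <- d >= 1
    if (!any(connected & types == 1) || !any(connected & types == 0)) {
      return(NA_real_)
    }
    frac <- as.vector(net %*% types)[connected] / d[connected]
    tc <- types[connected]
    mean(frac[tc == 1]) - mean(frac[tc == 0])
  } else {
    idx <- which(upper.tri(net) & net == 1L, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NA_real_)
    t1 <- types[idx[, 1L]]
    t2 <- types[idx[, 2L]]
    m2 <- 2 * nrow(idx)
    ecc <- 2 * sum(t1 == 1 & t2 == 1) / m2
    edd <- 2 * sum(t1 == 0 & t2 == 0) / m2
    ecd <- sum(t1 != t2) / m2        # each direction
    aC <- ecc + ecd
    aD <- edd + ecd
    den <- 1 - (aC^2 + aD^2)
    if (den == 0) return(NA_real_)
    (ecc + edd - (aC^2 + aD^2)) / den
  }
}

#' Trailing-window summary of replicate time series
#'
#' Averages each recorded observable over a trailing window of generations
#' within each replicate (and any further grouping columns, e.g. grid-cell
#' parameters), then reports the mean and standard deviation across
#' replicates. This is the aggregation behind long-run frequencies such as
#' "average over the last 400 of 500 generations".
#'
#' @param series A tibble of per-generation records with a `replicate`
#'   column, as returned by [run_replicates()] or [run_grid()]
#'   trajectories.
#' @param trailing_frac Fraction of the recorded generations (from the
#'   end) to average over; ignored when `window` is given.
#' @param window Number of trailing generations to average over.
#' @param by Character vector of extra grouping columns (grid-cell
#'   parameters); summaries are computed per group.
#' @return A tibble with one row per group: for each observable its
#'   cross-replicate mean and, with more than one replicate, its `_sd`
#'   companion, plus `n_replicates`.
#' @export
summarize_window <- function(series, trailing_frac = 0.8, window = NULL,
                             by = character()) {
  if (!"replicate" %in% names(series)) {
    series <- dplyr::mutate(series, replicate = 1L)
  }
  gmax <- max(series$generation)
  gmin <- min(series$generation)
  span <- gmax - gmin + 1
  if (is.null(window)) {
    window <- ceiling(span * trailing_frac)
  }
  if (window > span) {
    stop("`window` is longer than the recorded series", call. = FALSE)
  }
  cutoff <- gmax - window
  vars <- intersect(
    c("coop_freq", "mean_pn", "mean_pr", "mean_degree", "mean_payoff",
      "mean_fitness", "assortment", "assort_newman"),
    names(series))
  per_rep <- series |>
    dplyr::filter(.data$generation > cutoff) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "replicate")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  out <- per_rep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(vars),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         sd = ~ sd(.x)),
                    .names = "{.col}__{.fn}"),
      n_replicates = dplyr::n(),
      .groups = "drop")
  names(out) <- sub("__mean$", "", names(out))
  names(out) <- sub("__sd$", "_sd", names(out))
  out
}
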