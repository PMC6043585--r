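grid_axes <- c("p_n", "p_r", "B", "C", "D", "C_link", "D_pl")

apply_axis <- function(game, evo, axis, value) {
  switch(axis,
         p_n = { evo$init_pn <- value; list(game, evo) },
         p_r = { evo$init_pr <- value; list(game, evo) },
         B = { game$B <- value; list(game, evo) },
         C = { game$C <- value; list(game, evo) },
         D = { game$D <- value; list(game, evo) },
         C_link = { game$C_link <- value; list(game, evo) },
         D_pl = { game$D_pl <- value; list(game, evo) },
         stop(sprintf("unknown sweep axis `%s`; recognised axes: %s",
                      axis, paste(grid_axes, collapse = ", ")),
              call. = FALSE))
}

#' Sweep a one- or two-dimensional parameter grid
#'
#' Runs `replicates` independent simulations in every cell of a parameter
#' grid and returns the trailing-window summary per cell. Recognised axes
#' are the linking probabilities `p_n` and `p_r` (they set the initial
#' means; whether a trait actually evolves is governed by `evo`) and the
#' game parameters `B`, `C`, `D`, `C_link`, `D_pl`. This covers the
#' canonical experiments: fixed-trait `p_n` x `p_r` grids with and without
#' synergy, coevolving `B` x `C_link` and `D` x `C_link` grids, and the
#' fixed-`p_n` x `C_link` grid with evolving `p_r`.
#'
#' Per-cell, per-replicate seeds are a deterministic function of
#' `(seed, cell, replicate)`, so results do not depend on evaluation
#' order.
#'
#' @param grid Named list of one or two axes mapping an axis name to its
#'   value vector, e.g. `list(p_r = c(0.001, 0.1), p_n = c(0.1, 0.9))`.
#' @inheritParams run_replicates
#' @param trailing_frac,window Trailing averaging window, see
#'   [summarize_window()].
#' @param keep_series Also return the full per-generation records as
#'   attribute `"series"`?
#' @param ... Passed on to [run_simulation()].
#' @return A tibble with one row per grid cell: the axis columns, the
#'   cross-replicate mean of each observable over the trailing window, its
#'   `_sd` companion, and `n_replicates`.
#' @examples
#' \donttest{
#' run_grid(list(p_r = c(0.001, 0.3)), n = 50, generations = 50,
#'          replicates = 2, seed = 1,
#'          evo = evo_params(init_pn = 0.5))
#' }
#' @export
run_grid <- function(grid, replicates, seed, n = 100, generations = 500,
                     game = game_params(), evo = evo_params(),
                     trailing_frac = 0.8, window = NULL,
                     keep_series = FALSE, ...) {
  stopifnot(is.list(grid), length(grid) >= 1, length(grid) <= 2)
  axes <- names(grid)
  bad <- setdiff(axes, grid_axes)
  if (length(bad)) {
    stop(sprintf("unknown sweep axis `%s`; recognised axes: %s",
                 bad[1], paste(grid_axes, collapse = ", ")),
         call. = FALSE)
  }
  cells <- tidyr::expand_grid(!!!grid)
  seeds <- matrix(replicate_seeds(seed, nrow(cells) * replicates),
                  nrow = nrow(cells))
  series <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    g <- game
    e <- evo
    for (a in axes) {
      upd <- apply_axis(g, e, a, cells[[a]][ci])
      g <- upd[[1]]
      e <- upd[[2]]
    }
    purrr::map_dfr(seq_len(replicates), function(ri) {
      sim <- run_simulation(n = n, generations = generations, game = g,
                            evo = e, seed = seeds[ci, ri], ...)
      out <- dplyr::mutate(strip_sim(sim), replicate = ri,
                           .before = 1L)
      for (a in rev(axes)) out <- dplyr::mutate(out, !!a := cells[[a]][ci],
                                                .before = 1L)
      out
    })
  })
  summary <- summarize_window(series, trailing_frac = trailing_frac,
                              window = window, by = axes)
  if (keep_series) attr(summary, "series") <- series
  summary
}

#' Replicate trajectory bundle for coevolution runs
#'
#' Runs replicate simulations and returns every per-generation record (not
#' just trailing summaries) together with the cross-replicate mean
#' trajectory, the view used to show how cooperation establishes and then
#' collapses as `p_r` evolves upward.
#'
#' @inheritParams run_replicates
#' @param ... Passed on to [run_simulation()].
#' @return A tibble of class `"coop_traj"`: per-generation records with a
#'   `replicate` column; the cross-replicate mean trajectory is attached
#'   as attribute `"mean_trajectory"` (also a tibble).
#' @export
run_trajectories <- function(replicates, seed, n = 100, generations = 2000,
                             game = game_params(),
                             evo = evo_params(evolve_pn = TRUE,
                                              evolve_pr = TRUE,
                                              init_pr = 0.001), ...) {
  series <- run_replicates(replicates = replicates, seed = seed, n = n,
                           generations = generations, game = game,
                           evo = evo, ...)
  obs_cols <- setdiff(names(series)[vapply(series, is.numeric, logical(1))],
                      c("replicate", "generation"))
  mean_traj <- series |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(obs_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  attr(series, "mean_trajectory") <- mean_traj
  class(series) <- c("coop_traj", class(series))
  series
}

#' Cross-replicate mean trajectory
#'
#' @param traj A `"coop_traj"` tibble from [run_trajectories()].
#' @return A tibble with one row per generation.
#' @export
mean_trajectory <- function(traj) {
  mt <- attr(traj, "mean_trajectory")
  if (is.null(mt)) stop("`traj` carries no mean trajectory", call. = FALSE)
  mt
}

#' Named desk-scale experiment presets
#'
#' Scaled-down reconstructions of the canonical experiments, sized so a
#' preset finishes in minutes on one core. They are qualitative, not
#' exact, reproductions: run lengths are shorter than the originals and
#' the coevolution presets compress the mutational timescale (see the
#' methods vignette). Each preset is a list of arguments for [run_grid()]
#' or [run_trajectories()].
#'
#' * `fig1_smoke` — fixed-trait `p_n` x `p_r` grid, no synergy.
#' * `fig2_smoke` — fixed-trait grid with synergy `D = 1`.
#' * `fig3_smoke` — coevolution trajectories from low `p_r`.
#' * `fig4_smoke` — coevolving `B` x `C_link` grid.
#' * `fig5_smoke` — coevolving `D` x `C_link` grid (weak selection).
#' * `fig6_smoke` — fixed `p_n` x `C_link` grid with evolving `p_r`.
#'
#' @param name Preset name.
#' @return A list with elements `fn` (`"run_grid"` or
#'   `"run_trajectories"`) and `args`.
#' @export
preset <- function(name = c("fig1_smoke", "fig2_smoke", "fig3_smoke",
                            "fig4_smoke", "fig5_smoke", "fig6_smoke")) {
  name <- match.arg(name)
  fixed <- evo_params(mu = 0.001, evolve_pn = FALSE, evolve_pr = FALSE)
  coev <- evo_params(mu = 0.001, mu_l = 0.01, sigma_n = 0.01,
                     sigma_r = 0.01, evolve_pn = TRUE, evolve_pr = TRUE,
                     init_pn = 0.5, init_pr = 1e-4)
  switch(
    name,
    fig1_smoke = list(fn = "run_grid", args = list(
      grid = list(p_r = c(0.001, 0.01, 0.1, 0.3),
                  p_n = c(0.1, 0.5, 0.9)),
      n = 100, generations = 500, replicates = 10,
      game = game_params(B = 2, C = 0.5, D = 0, delta = 0.1),
      evo = fixed)),
    fig2_smoke = list(fn = "run_grid", args = list(
      grid = list(p_r = c(0.001, 0.01, 0.1, 0.3),
                  p_n = c(0.1, 0.5, 0.9)),
      n = 100, generations = 500, replicates = 10,
      game = game_params(B = 2, C = 0.5, D = 1, delta = 0.1),
      evo = fixed)),
    fig3_smoke = list(fn = "run_trajectories", args = list(
      n = 100, generations = 2000, replicates = 20,
      game = game_params(B = 2, C = 0.5, D = 0, delta = 0.1),
      evo = evo_params(mu = 0.001, mu_l = 0.01, sigma_n = 0.01,
                       sigma_r = 0.01, evolve_pn = TRUE,
                       evolve_pr = TRUE, init_pn = 0.5,
                       init_pr = 0.001))),
    fig4_smoke = list(fn = "run_grid", args = list(
      grid = list(C_link = c(0, 0.2, 0.4), B = c(1, 2, 4)),
      n = 100, generations = 5000, replicates = 10,
      game = game_params(B = 2, C = 0.5, D = 0, delta = 0.1),
      evo = coev)),
    fig5_smoke = list(fn = "run_grid", args = list(
      grid = list(C_link = c(0, 0.2, 0.4), D = c(0, 1, 2)),
      n = 100, generations = 5000, replicates = 10,
      game = game_params(B = 2, C = 0.5, D = 0, delta = 0.01),
      evo = coev)),
    fig6_smoke = list(fn = "run_grid", args = list(
      grid = list(C_link = c(0, 0.2, 0.4), p_n = c(0.1, 0.5, 0.9)),
      n = 100, generations = 5000, replicates = 10,
      game = game_params(B = 2, C = 0.5, D = 0, delta = 0.1),
      evo = evo_params(mu = 0.001, mu_l = 0.01, sigma_n = 0.01,
                       sigma_r = 0.01, evolve_pn = FALSE,
                       evolve_pr = TRUE, init_pn = 0.5,
                       init_pr = 1e-4))))
}

#' Run a named preset
#'
#' @param preset_name Preset name, see [preset()].
#' @param seed Base seed.
#' @param ... Overrides for the preset's arguments (e.g. `replicates`,
#'   `generations`, `n`).
#' @return The result of the underlying [run_grid()] or
#'   [run_trajectories()] call.
#' @export
run_preset <- function(preset_name, seed, ...) {
  p <- preset(preset_name)
  args <- utils::modifyList(p$args, list(...))
  args$seed <- seed
  do.call(p$fn, args)
}

#' Write a machine-readable run manifest
#'
#' Records the fully resolved configuration of an invocation (parameters,
#' seeds, package version) as JSON so any output can be regenerated
#' exactly.
#'
#' @param path Output path.
#' @param config Named list of configuration values.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the `jsonlite` package is required to write manifests",
         call. = FALSE)
  }
  config$package_version <- as.character(utils::packageVersion("coopnet"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
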