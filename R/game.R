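#' Game and selection parameters
#'
#' Bundles the payoff and selection parameters of the cooperation game.
#' Under the default `"diluted"` payoff model a cooperator pays a fixed
#' cost `C` and distributes a total benefit `B` equally among its
#' neighbours, so each partner receives `B / degree`; two connected
#' cooperators additionally each receive the synergy `D` divided by the
#' product of their degrees, and every individual pays `C_link` per
#' maintained edge:
#' \deqn{u_i = \sum_{j \ne i} p_j a_{ij}\left(\frac{B}{d_j} +
#'   p_i \frac{D}{d_i d_j}\right) - p_i C - d_i C_{link}.}
#' The `"per_link"` variant is a classical prisoner's dilemma on the
#' network: a cooperator gives a fixed benefit `B` to each partner and pays
#' the cost `C` per partner, with optional per-link synergy `D_pl`.
#' Payoffs map to fitness as \eqn{w = (1+\delta)^u}.
#'
#' @param B Benefit from cooperation. Total per cooperator in the diluted
#'   model; per link in the per-link model.
#' @param C Cost of cooperating (fixed, or per link in the per-link model).
#' @param D Synergistic benefit between connected cooperators (diluted
#'   model; divided by the degree product).
#' @param C_link Per-link maintenance cost paid by every individual,
#'   regardless of type. Must be non-negative.
#' @param delta Selection strength \eqn{\delta \ge 0}; 0 gives neutral
#'   dynamics.
#' @param payoff_model `"diluted"` (default) or `"per_link"`.
#' @param D_pl Per-link synergy of the per-link variant (default 0).
#' @return A list of class `"game_params"`.
#' @examples
#' game_params(B = 2, C = 0.5)
#' @export
game_params <- function(B = 2, C = 0.5, D = 0, C_link = 0, delta = 0.1,
                        payoff_model = c("diluted", "per_link"), D_pl = 0) {
  payoff_model <- match.arg(payoff_model)
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (C_link < 0) stop("`C_link` must be >= 0", call. = FALSE)
  structure(
    list(B = B, C = C, D = D, C_link = C_link, delta = delta,
         payoff_model = payoff_model, D_pl = D_pl),
    class = "game_params"
  )
}

#' @export
print.game_params <- function(x, ...) {
  cat("<game_params> model:", x$payoff_model,
      sprintf("B=%g C=%g D=%g C_link=%g delta=%g", x$B, x$C, x$D,
              x$C_link, x$delta),
      if (x$payoff_model == "per_link") sprintf("D_pl=%g", x$D_pl), "\n")
  invisible(x)
}

check_types <- function(types, n) {
  if (length(types) != n || !all(types %in% c(0, 1))) {
    stop("`types` must be a 0/1 allele vector, one entry per individual",
         call. = FALSE)
  }
  as.numeric(types)
}

#' Diluted-benefit payoffs
#'
#' Payoff of every living individual under the diluted model: each
#' cooperator's total benefit `B` is split equally among its partners, with
#' optional synergy `D` on cooperator–cooperator edges and a per-link cost
#' `C_link`. Isolated cooperators get `-C`; isolated defectors get 0. No
#' division by a zero degree can occur because a zero-degree individual has
#' no incident edges.
#'
#' @param net Symmetric 0/1 adjacency matrix.
#' @param types 0/1 allele vector (1 = cooperator).
#' @param params A [game_params()] object.
#' @return Numeric payoff vector, one entry per individual.
#' @examples
#' net <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)) # path 1-2-3
#' payoffs_diluted(net, c(1, 1, 0), game_params(B = 2, C = 0.5, D = 1))
#' @export
payoffs_diluted <- function(net, types, params) {
  check_network(net)
  types <- check_types(types, nrow(net))
  d <- rowSums(net)
  ds <- pmax(d, 1)  # safe divisor: zero-degree rows contribute nothing
  benefit <- as.vector(net %*% (types * params$B / ds))
  synergy <- types * params$D * as.vector(net %*% (types / ds)) / ds
  benefit + synergy - types * params$C - d * params$C_link
}

#' Per-link (prisoner's dilemma) payoffs
#'
#' Variant in which a cooperator provides a fixed benefit `B` to each
#' partner and pays a fixed cost `C` per partner, so benefits do not dilute
#' with degree. `D_pl` adds a constant synergy on cooperator–cooperator
#' edges; `C_link` is paid per edge by everyone.
#'
#' @inheritParams payoffs_diluted
#' @return Numeric payoff vector, one entry per individual.
#' @export
payoffs_per_link <- function(net, types, params) {
  check_network(net)
  types <- check_types(types, nrow(net))
  d <- rowSums(net)
  benefit <- as.vector(net %*% (types * params$B)) +
    types * params$D_pl * as.vector(net %*% types)
  benefit - types * d * params$C - d * params$C_link
}

#' Compute payoffs under the configured payoff model
#'
#' @inheritParams payoffs_diluted
#' @return Numeric payoff vector.
#' @export
payoffs <- function(net, types, params) {
  switch(params$payoff_model,
         diluted = payoffs_diluted(net, types, params),
         per_link = payoffs_per_link(net, types, params))
}

#' Map payoffs to fitness
#'
#' \eqn{w_i = (1+\delta)^{u_i}}, computed as `exp(u * log1p(delta))` so
#' negative payoffs are handled without pow-domain edge cases. Fitness is
#' strictly positive; `delta = 0` gives fitness 1 for everyone (neutral
#' dynamics).
#'
#' @param u Numeric payoff vector.
#' @param delta Selection strength, must be `>= 0`.
#' @return Numeric fitness vector, elementwise positive.
#' @export
fitness_from_payoff <- function(u, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    stop("`delta` must be a single value >= 0", call. = FALSE)
  }
  exp(u * log1p(delta))
}

#' Reproduction lottery over survivors
#'
#' Probability that each survivor is chosen as the parent of the
#' replacement, proportional to fitness cached from the end of the previous
#' time step. The individual just selected to die is excluded by default
#' ("another individual is selected to reproduce"); set
#' `include_dead = TRUE` for the inclusive reading, a sensitivity switch.
#'
#' @param w Positive fitness vector for all `N` individuals.
#' @param dead Index of the dying individual.
#' @param include_dead Keep the dying individual in the lottery?
#' @return Numeric probability vector of length `N` summing to 1; the dead
#'   individual's entry is 0 unless `include_dead`.
#' @export
reproduction_probabilities <- function(w, dead, include_dead = FALSE) {
  if (any(w < 0) || all(w == 0)) {
    stop("fitness weights must be non-negative and not all zero",
         call. = FALSE)
  }
  p <- w
  if (!include_dead) p[dead] <- 0
  if (sum(p) <= 0) stop("no survivor has positive fitness", call. = FALSE)
  p / sum(p)
}
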