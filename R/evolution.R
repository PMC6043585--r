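#' Inheritance and mutation parameters
#'
#' Controls how the cooperation allele and the linking traits are passed
#' from parent to offspring. At each birth the offspring copies the
#' parent's allele with probability `1 - mu` and switches otherwise. When a
#' linking trait evolves, it mutates independently with probability `mu_l`
#' by a Gaussian step (sd `sigma_n` for `p_n`, `sigma_r` for `p_r`) and is
#' clamped to \[0, 1\]; non-evolving traits are copied verbatim.
#'
#' The three scenarios of interest are encoded by the flags:
#' fixed traits (`evolve_pn = FALSE, evolve_pr = FALSE`), full coevolution
#' (both `TRUE`), and exogenously fixed social inheritance with evolving
#' random linking (`evolve_pn = FALSE, evolve_pr = TRUE`).
#'
#' @param mu Allele mutation probability per birth.
#' @param mu_l Linking-trait mutation probability per trait per birth.
#' @param sigma_n,sigma_r Mutation-step standard deviations for `p_n` and
#'   `p_r`.
#' @param evolve_pn,evolve_pr Which linking traits are heritable and
#'   mutable.
#' @param init_pn,init_pr Initial mean linking probabilities. Evolving
#'   traits are initialised per individual from a normal distribution with
#'   these means and the mutational standard deviations, clamped to
#'   \[0, 1\]; fixed traits stay at the mean for everyone.
#' @return A list of class `"evo_params"`.
#' @examples
#' evo_params(evolve_pr = TRUE, init_pr = 0.001)
#' @export
evo_params <- function(mu = 0.001, mu_l = 0.001, sigma_n = 0.01,
                       sigma_r = 0.01, evolve_pn = FALSE, evolve_pr = FALSE,
                       init_pn = 0.5, init_pr = 1e-4) {
  check_probability(mu, "mu")
  check_probability(mu_l, "mu_l")
  check_probability(init_pn, "init_pn")
  check_probability(init_pr, "init_pr")
  if (sigma_n < 0 || sigma_r < 0) {
    stop("mutation-step standard deviations must be >= 0", call. = FALSE)
  }
  structure(
    list(mu = mu, mu_l = mu_l, sigma_n = sigma_n, sigma_r = sigma_r,
         evolve_pn = isTRUE(evolve_pn), evolve_pr = isTRUE(evolve_pr),
         init_pn = init_pn, init_pr = init_pr),
    class = "evo_params"
  )
}

#' @export
print.evo_params <- function(x, ...) {
  scen <- if (x$evolve_pn && x$evolve_pr) "coevolving p_n, p_r"
  else if (x$evolve_pr) "fixed p_n, evolving p_r"
  else if (x$evolve_pn) "evolving p_n, fixed p_r"
  else "fixed traits"
  cat("<evo_params>", scen, "\n",
      sprintf(" mu=%g mu_l=%g sigma_n=%g sigma_r=%g init_pn=%g init_pr=%g\n",
              x$mu, x$mu_l, x$sigma_n, x$sigma_r, x$init_pn, x$init_pr))
  invisible(x)
}

#' Offspring cooperation allele
#'
#' Copies the parent's allele with probability `1 - mu`, switches to the
#' other type with probability `mu`.
#'
#' @param parent_type 0 or 1.
#' @param mu Mutation probability.
#' @return 0 or 1.
#' @export
mutate_type <- function(parent_type, mu) {
  if (!parent_type %in% c(0, 1)) {
    stop("`parent_type` must be 0 or 1", call. = FALSE)
  }
  check_probability(mu, "mu")
  if (runif(1) < mu) 1 - parent_type else parent_type
}

#' Offspring linking traits
#'
#' Each evolving trait independently mutates with probability `mu_l` by a
#' zero-mean Gaussian step; values outside \[0, 1\] are set to the nearest
#' boundary. Traits flagged non-evolving are copied verbatim.
#'
#' @param traits Named numeric vector with entries `p_n` and `p_r`.
#' @param evo An [evo_params()] object.
#' @return Named numeric vector with entries `p_n` and `p_r`.
#' @export
mutate_traits <- function(traits, evo) {
  p_n <- traits[["p_n"]]
  p_r <- traits[["p_r"]]
  if (evo$evolve_pn && runif(1) < evo$mu_l) {
    p_n <- min(1, max(0, p_n + rnorm(1, 0, evo$sigma_n)))
  }
  if (evo$evolve_pr && runif(1) < evo$mu_l) {
    p_r <- min(1, max(0, p_r + rnorm(1, 0, evo$sigma_r)))
  }
  c(p_n = p_n, p_r = p_r)
}

#' One death-birth time step (reference implementation)
#'
#' Executes a single event in plain R, in the model's fixed order:
#' (1) a uniformly random individual dies; (2) a parent is drawn among the
#' survivors with probability proportional to the fitness cached at the end
#' of the previous step; (3) the dead individual and its edges are removed;
#' (4) the newborn takes the freed slot with a possibly mutated allele and
#' linking traits; (5) the newborn is wired by [newborn_links()] using its
#' own traits; (6) payoffs and fitness of all individuals are recomputed
#' and cached. This is the readable small-scale counterpart of the compiled
#' engine used by [run_simulation()].
#'
#' @param state A list with elements `net`, `types`, `p_n`, `p_r`,
#'   `payoffs`, `fitness`, `step` (as produced by this function or
#'   assembled by hand; `payoffs`/`fitness` may be omitted on the first
#'   call, in which case they are computed from the current state).
#' @param game A [game_params()] object.
#' @param evo An [evo_params()] object.
#' @param include_dead Keep the dying individual in the parent lottery?
#' @return The updated state list.
#' @export
sim_step <- function(state, game, evo, include_dead = FALSE) {
  n <- nrow(state$net)
  if (is.null(state$fitness)) {
    state$payoffs <- payoffs(state$net, state$types, game)
    state$fitness <- fitness_from_payoff(state$payoffs, game$delta)
  }
  dead <- sample.int(n, 1L)
  prob <- reproduction_probabilities(state$fitness, dead, include_dead)
  parent <- sample.int(n, 1L, prob = prob)
  child_type <- mutate_type(state$types[parent], evo$mu)
  child_traits <- mutate_traits(
    c(p_n = state$p_n[parent], p_r = state$p_r[parent]), evo)
  state$net <- replace_individual(state$net, dead, parent,
                                  child_traits[["p_n"]],
                                  child_traits[["p_r"]])
  state$types[dead] <- child_type
  state$p_n[dead] <- child_traits[["p_n"]]
  state$p_r[dead] <- child_traits[["p_r"]]
  state$payoffs <- payoffs(state$net, state$types, game)
  state$fitness <- fitness_from_payoff(state$payoffs, game$delta)
  state$step <- (state$step %||% 0L) + 1L
  state
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# records only, without the state/config attributes or the coop_sim class
strip_sim <- function(sim) {
  out <- tibble::as_tibble(sim)
  attr(out, "final_state") <- NULL
  attr(out, "config") <- NULL
  class(out) <- setdiff(class(out), "coop_sim")
  out
}

#' Run one replicate of the evolutionary simulation
#'
#' Protocol: (1) sample an Erdős–Rényi network of density `p0`;
#' (2) run a selection-free burn-in of `burnin` generations (uniform
#' parent choice, traits at their initial means) so the network reaches the
#' stationary structure of the social-inheritance process; (3) assign
#' cooperation alleles independently with probability 0.5, and — for
#' evolving scenarios — draw each individual's linking traits around the
#' initial means with the mutational standard deviations, clamped to
#' \[0, 1\]; (4) run `generations` x `n` selection steps, recording
#' observables once per `record_every` generations (one generation = `n`
#' death-birth events). The post-burn-in state is recorded as
#' generation 0.
#'
#' @param n Population size.
#' @param generations Number of selection generations to run.
#' @param game A [game_params()] object.
#' @param evo An [evo_params()] object.
#' @param p0 Initial Erdős–Rényi density (erased by the burn-in).
#' @param burnin Burn-in length in generations (default 20).
#' @param record_every Generations between recorded rows.
#' @param seed Optional integer seed (`set.seed()` is called when given);
#'   identical seed and configuration give bit-identical trajectories.
#' @param include_dead_in_lottery Sensitivity switch for the reproduction
#'   lottery denominator.
#' @param stop_at_fixation Stop as soon as the cooperation allele fixes or
#'   is lost (only meaningful with `mu = 0`).
#' @param check_invariants Verify adjacency symmetry, zero diagonal, degree
#'   bookkeeping, allele and trait ranges after every event (slow; for
#'   instrumented runs).
#' @return A tibble of class `"coop_sim"` with one row per recorded
#'   generation and columns `generation`, `coop_freq`, `mean_pn`,
#'   `mean_pr`, `mean_degree`, `mean_payoff`, `mean_fitness`,
#'   `assortment` (neighbour-fraction difference) and `assort_newman`
#'   (nominal edge assortativity). The final population state (adjacency,
#'   types, traits, payoffs, fitness, fixation flag) is attached as
#'   attribute `"final_state"`, the resolved configuration as `"config"`.
#' @examples
#' sim <- run_simulation(n = 30, generations = 10, seed = 1,
#'                       game = game_params(delta = 0),
#'                       evo = evo_params(init_pr = 0.01))
#' sim
#' @export
run_simulation <- function(n = 100, generations = 500,
                           game = game_params(), evo = evo_params(),
                           p0 = 0.1, burnin = 20, record_every = 1,
                           seed = NULL, include_dead_in_lottery = FALSE,
                           stop_at_fixation = FALSE,
                           check_invariants = FALSE) {
  if (generations < 0) stop("`generations` must be >= 0", call. = FALSE)
  if (record_every < 1) stop("`record_every` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- .engine_run(
    n = as.integer(n), p0 = p0, burnin_gens = as.integer(burnin),
    generations = as.integer(generations),
    B = game$B, C = game$C, D = game$D, Dpl = game$D_pl,
    Clink = game$C_link, delta = game$delta,
    per_link = identical(game$payoff_model, "per_link"),
    mu = evo$mu, mu_l = evo$mu_l,
    sigma_n = evo$sigma_n, sigma_r = evo$sigma_r,
    evolve_pn = evo$evolve_pn, evolve_pr = evo$evolve_pr,
    init_pn = evo$init_pn, init_pr = evo$init_pr,
    record_every = as.integer(record_every),
    include_dead_in_lottery = include_dead_in_lottery,
    stop_at_fixation = stop_at_fixation,
    check_invariants = check_invariants)
  out <- tibble::as_tibble(as.data.frame(res$records))
  attr(out, "final_state") <- res[c("adjacency", "types", "p_n", "p_r",
                                    "payoffs", "fitness", "fixation",
                                    "generations_run", "steps")]
  attr(out, "config") <- list(
    n = n, generations = generations, p0 = p0, burnin = burnin,
    record_every = record_every, seed = seed,
    include_dead_in_lottery = include_dead_in_lottery,
    game = game, evo = evo)
  class(out) <- c("coop_sim", class(out))
  out
}

#' Final population state of a simulation
#'
#' @param sim A `"coop_sim"` tibble from [run_simulation()].
#' @return A list with the final adjacency matrix, allele vector, linking
#'   traits, cached payoffs and fitness, the fixation flag (1 cooperation
#'   fixed, 0 lost, NA neither) and step counters.
#' @export
final_state <- function(sim) {
  st <- attr(sim, "final_state")
  if (is.null(st)) stop("`sim` carries no final state", call. = FALSE)
  st
}

#' Deterministic per-replicate seeds
#'
#' Derives `k` independent replicate seeds from one base seed; the i-th
#' seed depends only on `(seed, i)`, so replicates can run in any order or
#' in parallel and still reproduce.
#'
#' @param seed Base integer seed.
#' @param k Number of seeds.
#' @return Integer vector of length `k`.
#' @export
replicate_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Run independent replicate simulations
#'
#' Runs `replicates` independent copies of [run_simulation()], each with a
#' seed derived deterministically from `(seed, replicate)`, and binds the
#' recorded time series.
#'
#' @inheritParams run_simulation
#' @param replicates Number of independent replicates.
#' @param seed Base seed for [replicate_seeds()].
#' @param ... Passed on to [run_simulation()].
#' @return A tibble with the columns of [run_simulation()] plus
#'   `replicate`.
#' @export
run_replicates <- function(replicates, seed, n = 100, generations = 500,
                           game = game_params(), evo = evo_params(), ...) {
  seeds <- replicate_seeds(seed, replicates)
  purrr::map_dfr(seq_len(replicates), function(i) {
    sim <- run_simulation(n = n, generations = generations, game = game,
                          evo = evo, seed = seeds[i], ...)
    dplyr::mutate(strip_sim(sim), replicate = i, .before = 1L)
  })
}
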