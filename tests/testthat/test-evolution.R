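test_that("allele inheritance copies or flips at the mutation rate", {
  set.seed(1)
  expect_equal(mutate_type(1, mu = 0), 1)
  expect_equal(mutate_type(0, mu = 0), 0)
  expect_equal(mutate_type(1, mu = 1), 0)
  expect_equal(mutate_type(0, mu = 1), 1)
  mu <- 0.01
  n <- 50000
  flips <- sum(replicate(n, mutate_type(1, mu)) == 0)
  se <- sqrt(n * mu * (1 - mu))
  expect_lt(abs(flips - n * mu), 3 * se)
})

test_that("trait mutation is Gaussian, scenario-gated and clamped to [0,1]", {
  evo <- evo_params(mu_l = 0, evolve_pn = TRUE, evolve_pr = TRUE)
  expect_equal(mutate_traits(c(p_n = 0.3, p_r = 0.7), evo),
               c(p_n = 0.3, p_r = 0.7))

  # non-evolving traits are copied verbatim even with mu_l = 1
  fixed <- evo_params(mu_l = 1, evolve_pn = FALSE, evolve_pr = FALSE)
  set.seed(2)
  expect_equal(mutate_traits(c(p_n = 0.4, p_r = 0.2), fixed),
               c(p_n = 0.4, p_r = 0.2))

  # a mutation stepping past 1 lands on the boundary
  evo1 <- evo_params(mu_l = 1, sigma_r = 10, evolve_pr = TRUE)
  set.seed(3)
  out <- replicate(200, mutate_traits(c(p_n = 0.5, p_r = 0.995), evo1)[["p_r"]])
  expect_true(all(out >= 0 & out <= 1))
  expect_true(any(out == 1))
  expect_true(any(out == 0))

  # interior parent, small steps: offspring - parent has sd sigma_r
  evo2 <- evo_params(mu_l = 1, sigma_r = 0.01, evolve_pr = TRUE)
  set.seed(4)
  d <- replicate(5000,
                 mutate_traits(c(p_n = 0.5, p_r = 0.5), evo2)[["p_r"]]) - 0.5
  expect_lt(abs(sd(d) - 0.01), 3 * 0.01 / sqrt(2 * 5000))
  expect_lt(abs(mean(d)), 3 * 0.01 / sqrt(5000))
})

test_that("a single reference step conserves population size and structure", {
  set.seed(5)
  state <- list(net = initial_network(20, 0.2),
                types = sample(0:1, 20, replace = TRUE),
                p_n = rep(0.5, 20), p_r = rep(0.1, 20))
  game <- game_params(delta = 0.1)
  evo <- evo_params(mu = 0.01, mu_l = 0.1, evolve_pn = TRUE,
                    evolve_pr = TRUE)
  for (k in 1:50) {
    state <- sim_step(state, game, evo)
    expect_identical(dim(state$net), c(20L, 20L))
    expect_identical(state$net, t(state$net))
    expect_true(all(diag(state$net) == 0L))
    expect_true(all(state$types %in% 0:1))
    expect_true(all(state$p_n >= 0 & state$p_n <= 1))
    expect_true(all(state$p_r >= 0 & state$p_r <= 1))
    # cached payoffs correspond to the current network and types
    expect_equal(state$payoffs, payoffs(state$net, state$types, game))
  }
  expect_equal(state$step, 50L)
})

test_that("identical seed and configuration give bit-identical trajectories", {
  run <- function() {
    run_simulation(n = 40, generations = 30, seed = 99,
                   game = game_params(B = 2, C = 0.5, delta = 0.1),
                   evo = evo_params(mu = 0.001, mu_l = 0.01,
                                    evolve_pn = TRUE, evolve_pr = TRUE,
                                    init_pr = 0.001))
  }
  a <- run()
  b <- run()
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(final_state(a), final_state(b))
})

test_that("a run with zero selection generations returns only the initial record", {
  sim <- run_simulation(n = 60, generations = 0, seed = 12,
                        game = game_params(delta = 0),
                        evo = evo_params(init_pr = 0.01))
  expect_equal(nrow(sim), 1L)
  expect_equal(sim$generation, 0)
  # alleles were assigned at expected frequency 0.5
  expect_gte(sim$coop_freq, 0)
  expect_lte(sim$coop_freq, 1)
  expect_equal(sim$coop_freq * 60, round(sim$coop_freq * 60))
})

test_that("post-burn-in allele frequency is centred on one half", {
  set.seed(31)
  freqs <- vapply(1:40, function(i) {
    run_simulation(n = 50, generations = 0, seed = 1000 + i,
                   game = game_params(delta = 0),
                   evo = evo_params(init_pr = 0.01))$coop_freq
  }, numeric(1))
  se <- sqrt(0.25 / 50) / sqrt(40)
  expect_lt(abs(mean(freqs) - 0.5), 3 * se)
})

test_that("neutral evolving traits perform an unbiased random walk", {
  sims <- run_replicates(replicates = 20, seed = 17, n = 50,
                         generations = 100,
                         game = game_params(delta = 0),
                         evo = evo_params(mu = 0, mu_l = 0.1,
                                          sigma_n = 0.01, sigma_r = 0.01,
                                          evolve_pn = TRUE, evolve_pr = TRUE,
                                          init_pn = 0.5, init_pr = 0.5))
  finals <- dplyr::filter(sims, generation == 100)
  # drift in either trait should be statistically indistinguishable from 0
  expect_lt(abs(mean(finals$mean_pn) - 0.5),
            3 * sd(finals$mean_pn) / sqrt(20) + 1e-8)
  expect_lt(abs(mean(finals$mean_pr) - 0.5),
            3 * sd(finals$mean_pr) / sqrt(20) + 1e-8)
})

test_that("tree-limit wiring (p_n = p_r = 0) drives mean degree to one", {
  sims <- run_replicates(replicates = 5, seed = 23, n = 50,
                         generations = 150,
                         game = game_params(delta = 0),
                         evo = evo_params(mu = 0, init_pn = 0, init_pr = 0))
  late <- dplyr::filter(sims, generation > 100)
  # each newborn adds exactly one edge; a death removes mean-degree edges
  # on average, so the stationary mean degree is 1
  expect_lt(abs(mean(late$mean_degree) - 1), 0.3)
})

test_that("instrumented runs pass per-event structural verification", {
  expect_no_error(
    run_simulation(n = 30, generations = 5, seed = 3,
                   game = game_params(B = 2, C = 0.5, C_link = 0.1,
                                      delta = 0.2),
                   evo = evo_params(mu = 0.05, mu_l = 0.5, sigma_n = 0.3,
                                    sigma_r = 0.3, evolve_pn = TRUE,
                                    evolve_pr = TRUE, init_pr = 0.2),
                   check_invariants = TRUE))
  expect_no_error(
    run_simulation(n = 20, generations = 5, seed = 4,
                   game = game_params(payoff_model = "per_link", B = 1,
                                      C = 0.5, delta = 0.1),
                   evo = evo_params(),
                   check_invariants = TRUE))
})

test_that("the final state is consistent with the recorded last generation", {
  sim <- run_simulation(n = 40, generations = 25, seed = 8,
                        game = game_params(delta = 0.1),
                        evo = evo_params(init_pr = 0.01))
  st <- final_state(sim)
  last <- sim[nrow(sim), ]
  expect_equal(mean(st$types), last$coop_freq)
  expect_equal(mean(rowSums(st$adjacency)), last$mean_degree)
  expect_equal(mean(st$payoffs), last$mean_payoff)
  # cached payoffs are exactly the game's payoffs on the final network
  expect_equal(st$payoffs,
               payoffs(st$adjacency, st$types, game_params(delta = 0.1)),
               tolerance = 1e-12)
  expect_equal(st$fitness, fitness_from_payoff(st$payoffs, 0.1),
               tolerance = 1e-12)
})

test_that("post-burn-in network structure is insensitive to the seeding density", {
  mean_deg <- vapply(c(0.05, 0.1, 0.5), function(p0) {
    sims <- run_replicates(replicates = 5, seed = 61, n = 100,
                           generations = 50, p0 = p0,
                           game = game_params(delta = 0),
                           evo = evo_params(mu = 0, init_pn = 0.5,
                                            init_pr = 0.01))
    mean(dplyr::filter(sims, generation > 10)$mean_degree)
  }, numeric(1))
  expect_lt(diff(range(mean_deg)) / mean(mean_deg), 0.2)
})
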