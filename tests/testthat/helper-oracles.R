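# Independent brute-force oracles used across the suite. These are written
# from the model definition, not from the package internals, and stay
# deliberately naive.

# per-individual, per-neighbour double loop over Eq-style payoffs
oracle_payoffs <- function(net, types, params) {
  per_link <- identical(params$payoff_model, "per_link")
  n <- nrow(net)
  d <- rowSums(net)
  u <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i || net[i, j] == 0) next
      if (per_link) {
        u[i] <- u[i] + types[j] * params$B +
          types[i] * types[j] * params$D_pl
      } else {
        u[i] <- u[i] + types[j] *
          (params$B / d[j] + types[i] * params$D / (d[i] * d[j]))
      }
    }
    cost_c <- if (per_link) types[i] * d[i] * params$C else types[i] * params$C
    u[i] <- u[i] - cost_c - d[i] * params$C_link
  }
  u
}

# per-candidate Bernoulli rejection implementation of the newborn rule
oracle_newborn_size <- function(net, parent, p_n, p_r) {
  n <- nrow(net)
  size <- 1L
  for (j in seq_len(n)) {
    if (j == parent) next
    p <- if (net[parent, j] == 1) p_n else p_r
    if (runif(1) < p) size <- size + 1L
  }
  size
}

# cumulative-sum inverse-transform sampler for the reproduction lottery
oracle_lottery_draw <- function(prob) {
  cs <- cumsum(prob)
  findInterval(runif(1), cs) + 1L
}

random_instance <- function(n_max = 50, per_link = FALSE) {
  n <- sample(3:n_max, 1)
  net <- initial_network(n, runif(1, 0, 0.6))
  types <- sample(0:1, n, replace = TRUE)
  params <- game_params(B = runif(1, 0, 4), C = runif(1, 0, 1),
                        D = runif(1, 0, 2), C_link = runif(1, 0, 0.5),
                        delta = 0.1,
                        payoff_model = if (per_link) "per_link" else "diluted",
                        D_pl = runif(1, 0, 1))
  list(net = net, types = types, params = params)
}

path3 <- rbind(c(0L, 1L, 0L),
               c(1L, 0L, 1L),
               c(0L, 1L, 0L))
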