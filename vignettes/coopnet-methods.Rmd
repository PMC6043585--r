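---
title: "Methods: cooperation on dynamic networks with social inheritance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cooperation on dynamic networks with social inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`coopnet` simulates a population of constant size $N$ living on a binary,
undirected, dynamic social network. The network changes only through
death–birth events. At each time step:

1. a uniformly random individual dies (mortality is payoff-independent);
2. one of the $N-1$ survivors is chosen to reproduce with probability
   proportional to its fitness at the end of the previous time step,
   $\pi_i = w_i / \sum_{j \in \text{survivors}} w_j$;
3. the newborn replaces the dead individual and wires itself into the
   network: it links to its parent with certainty, to each of the parent's
   current neighbours independently with probability $p_n$ (*social
   inheritance*), and to each remaining individual independently with
   probability $p_r$ (*random linking*).

One *generation* is defined as $N$ death–birth events.

Each individual carries a binary cooperation allele $p_i \in \{0, 1\}$.
Under the default **diluted-benefit** game a cooperator spreads a fixed
total benefit $B$ equally over its $d_i$ partners and pays a fixed cost
$C$; connected cooperators can enjoy a synergy $D$ diluted by both
degrees; and every individual pays a maintenance cost $C_{link}$ per edge:

$$u_i = \sum_{j \ne i} p_j a_{ij}\left(\frac{B}{d_j} +
  p_i \frac{D}{d_i d_j}\right) - p_i C - d_i C_{link}.$$

The **per-link** variant (`payoff_model = "per_link"`) is the classical
networked prisoner's dilemma: benefit $B$ and cost $C$ are paid *per
partner*, with an optional per-link synergy `D_pl` (default 0, kept only
for completeness). Payoffs map to fitness through
$w_i = (1+\delta)^{u_i}$ with selection strength $\delta \ge 0$;
$\delta = 0$ gives neutral dynamics.

At each birth the offspring copies its parent's allele with probability
$1-\mu$ and switches otherwise. When a linking trait is heritable
(`evolve_pn`, `evolve_pr`), it mutates with probability $\mu_l$ by a
zero-mean Gaussian step (sd $\sigma_n$ or $\sigma_r$) and is clamped to
$[0,1]$; non-evolving traits are identical across the population and
copied verbatim. Three scenarios follow from the flags: fixed traits,
full coevolution, and exogenously fixed $p_n$ with evolving $p_r$.

## Simulation protocol

`run_simulation()` (a tidy wrapper over a compiled engine) proceeds as:

1. **Initialisation.** An Erdős–Rényi network $G(N, p_0)$ with
   $p_0 = 0.1$ by default.
2. **Burn-in.** 20 generations of the social-inheritance process without
   selection: uniform parent choice, no mutation, all traits at their
   initial means. This brings the network to the stationary structure of
   the neutral social-inheritance process, making the exact $p_0$
   immaterial (a test asserts the post-burn-in mean degree is insensitive
   to $p_0 \in \{0.05, 0.1, 0.5\}$).
3. **Allele and trait assignment.** Cooperation alleles are assigned
   independently with probability $0.5$. For evolving scenarios each
   individual's $p_n$ and $p_r$ are drawn from normal distributions with
   the initial means and the mutational standard deviations, clamped to
   $[0,1]$; fixed traits stay at the mean.
4. **Selection.** `generations` × $N$ steps, recording the observables
   once per generation (cooperation frequency, mean $p_n$, $p_r$, degree,
   payoff, fitness, and two assortment measures). The post-burn-in state
   is recorded as generation 0.

### Defaults and their rationale

| parameter | default | meaning |
|---|---|---|
| `B`, `C`, `D` | 2, 0.5, 0 | benefit, cost, synergy of the diluted game |
| `C_link` | 0 | per-edge maintenance cost |
| `delta` | 0.1 | selection strength |
| `mu` | 0.001 | allele mutation probability per birth |
| `mu_l` | 0.001 | trait mutation probability per trait per birth |
| `sigma_n`, `sigma_r` | 0.01 | trait mutation step (sd) |
| `init_pn`, `init_pr` | 0.5, 1e-4 | initial linking probabilities |
| `p0` | 0.1 | seeding density (erased by burn-in) |
| burn-in | 20 generations | neutral warm-up |

`init_pr` defaults to $10^{-4}$; coevolution trajectory studies
conventionally start from $10^{-3}$, and the trajectory preset
(`fig3_smoke`) does so. Initial values only set the starting point of the
trait random walks; the long-run dynamics move away from them quickly.

## Design choices where the model definition was open

* **Lottery denominator.** The dying individual is excluded from the
  reproduction lottery ("another individual" reproduces). The inclusive
  alternative is preserved behind `include_dead_in_lottery = TRUE` for
  sensitivity checks; with $N = 100$ the difference is a $1/N$ effect.
* **Removal before linking.** "Connected to the parent at the time of
  birth" is evaluated after the death that the birth replaces, so a tie
  to the dead individual can never be inherited and the newborn can never
  link to its own freed slot.
* **Newborn wiring uses the offspring's own traits**, i.e. possibly
  mutated values, not the parent's. The linking step is the offspring's
  action, and this is what places the linking traits under direct
  selection.
* **Payoff cache.** Payoffs and fitness are recomputed for everyone at
  the end of each step and used as the "previous step" fitness in the
  next lottery, so a newborn is eligible to reproduce from its first full
  step with the payoff earned from its initial connections.
* **Burn-in traits.** During the selection-free burn-in all individuals
  wire with the initial mean traits; individual trait variation is
  introduced only when selection is switched on, together with the
  alleles.
* **Assortment.** The primary measure is the mean fraction of cooperator
  neighbours among cooperators minus the same fraction among defectors
  (degree-0 individuals excluded; undefined when either class has no
  connected member). It directly expresses "cooperators interact
  disproportionately with cooperators", lies in $[-1,1]$, and is simple
  to reason about. Newman's nominal edge assortativity of the allele is
  recorded alongside (`assort_newman`) for robustness; the two agree in
  sign in practice.

## Numerical choices

* Fitness is computed as `exp(u * log1p(delta))` — identical to
  $(1+\delta)^u$ but well-behaved for negative payoffs.
* The diluted payoff sum only touches existing edges, so no division by a
  zero degree can occur; isolated cooperators earn exactly $-C$.
* All randomness flows through R's RNG, also inside the compiled engine,
  so `set.seed()` (or the `seed` argument) makes any run bit-reproducible.
  The draw order within a step is fixed and documented in the engine
  source: death, lottery, allele mutation, $p_n$ mutation, $p_r$
  mutation, then one uniform per wiring candidate in index order.
* Replicate seeds are derived once from the base seed
  (`replicate_seeds()`), so replicates and grid cells are independent of
  evaluation order and safe to parallelise externally.
* Trait clamping is applied at mutation time (and at trait
  initialisation), never afterwards, so recorded trait means are exact
  population means.

## Scaled experiments

The canonical long experiments run for $10^5$ generations; the presets
(`fig1_smoke` … `fig6_smoke`) and the package's acceptance checks are
desk-scale reconstructions chosen to finish in minutes on one core:
fixed-trait grids use 500 generations averaging the trailing 400 (the
original protocol), while coevolution runs use 2 000–5 000 generations
with trailing-80% averages. To make the linking traits move on that
shortened horizon, the desk-scale coevolution runs use the trajectory
study's trait mutation rate $\mu_l = 0.01$ rather than the grid studies'
$10^{-3}$ — a deliberate compression of the mutational timescale. These
reconstructions are qualitative: they reproduce directions and contrasts
(cooperation under low $p_r$; establishment-then-collapse under
coevolution; rescue of cooperation and suppression of $p_r$ by link
costs; neutral controls at $1/2$), not the exact long-run figures of the
full-scale protocol.

## What the generator does and does not emulate

All inputs are synthetic by construction: the simulator *is* the model.
Within the model, the tests demonstrate internal correctness (payoff
algebra against brute-force oracles, neutral martingale controls,
structural invariants after every event) and the qualitative phenomena
above. The model itself abstracts away much of real animal sociality:
binary ties without weights or decay, no active partner choice or link
breaking, payoff-independent mortality, non-overlapping trait classes,
and no demographic structure. Passing tests therefore support the
implementation and the model's internal logic, not claims about any
particular natural population.

## Known limitations

* The engine recomputes all payoffs after every event ($O(N^2)$ per
  step); this is exact and fast for $N$ up to a few hundred, but an
  incremental update would be needed for very large populations.
* `stop_at_fixation` is only meaningful with `mu = 0`; with mutation the
  allele frequency re-enters $(0,1)$.
* The assortment measures are undefined (recorded `NA`) whenever a class
  has no connected member — routinely the case near fixation; trailing
  averages use the defined values only.
```{r, eval = FALSE}
library(coopnet)
sim <- run_simulation(n = 100, generations = 500, seed = 1,
                      game = game_params(B = 2, C = 0.5, delta = 0.1),
                      evo = evo_params(mu = 0.001, init_pn = 0.5,
                                       init_pr = 0.001))
glance(sim)
autoplot(sim)
```
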