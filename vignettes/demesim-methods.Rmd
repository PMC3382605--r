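---
title: "Migration, structure and the fate of cooperation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migration, structure and the fate of cooperation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demesim)
```

## The model

`demesim` simulates an evolutionary prisoner's dilemma in a subdivided
population.  `N` individuals live in `D` demes of carrying capacity
`N0 = N / D`, each individual carrying one pure strategy — cooperate (C) or
defect (D) — and a scalar fitness.  Demes occupy the nodes of an undirected
migration network; edges are the only routes migrants can take.  Every
generation applies three stages, in this fixed order:

1. **Game stage.**  Within each deme the roster is randomly paired (a uniform
   perfect matching; with an odd roster one individual sits the round out) and
   every pair plays one round of the prisoner's dilemma with payoffs
   `T > R > P > S` and `2R > T + S`: mutual cooperation pays `R` to each,
   mutual defection `P`, and a defector meeting a cooperator takes the
   temptation `T` while the cooperator is left the sucker payoff `S`.
   Each paired individual's fitness is then updated by the learning rule

   `f(t+1) = (1 - w) f(t) + w G(t)`,

   where `G(t)` is the round payoff and `w` in `(0, 1]` weighs current
   experience against accumulated history.  The update is a convex
   combination, so fitness always stays inside the payoff range and its
   supremum is the largest payoff `T`; under a constant payoff it converges
   geometrically to that payoff.  With the default `w = 1/2` the iterates
   from an empty history are exactly `f(n) = G (1 - 2^-n)`.

2. **Migration.**  Each individual independently moves with probability `m`
   to a uniformly chosen neighbour deme, carrying strategy and fitness
   unchanged.  Individuals in isolated demes stay put; empty demes are legal
   destinations, which is the only way an extinct deme is recolonised.  Deme
   sizes after migration are unconstrained; the individual multiset is
   conserved exactly.

3. **Local selection.**  Independently in each deme: first every individual
   with fitness strictly below the elimination threshold `E` is removed
   (fitness exactly `E` survives — "below" is read literally); then the deme
   is restored to its carrying capacity.  A deme above `N0` is culled by
   repeatedly removing a least-fit member (ties broken uniformly at random);
   a deme below `N0` but non-empty undergoes a local expansion in which
   parents are drawn with replacement from the pre-expansion survivors with
   probability proportional to fitness, and each daughter inherits the
   parent's strategy but starts with fitness 0; a deme exactly at `N0` is
   untouched, and an empty deme stays empty.

The all-cooperator state and total extinction are absorbing: no rule
reintroduces a lost strategy.  An all-defector population is not short-cut to
extinction — whether it persists is left to the dynamics, since with
user-modified payoffs the punishment `P` may clear `E`.  Under the default
payoffs `P < E`, so pure defection decays to the punishment payoff and is
eliminated; this emergent extinction of defector-only populations is one of
the model's characteristic behaviours.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `T, R, P, S` | 1.5, 1, 0.1, 0 | payoff matrix (payoff units) |
| `E` | 0.4 | elimination threshold; must satisfy `E < R` |
| `w` | 1/2 | learning weight of the fitness update |
| `m` | — | per-individual migration probability per generation |
| `N`, `D` | 400, 20 | total population and deme count (`N0 = N / D`) |
| `init_coop` | 0.5 | founder cooperation probability (i.i.d. Bernoulli) |
| `init_fitness` | 0 | founder and newborn fitness |
| topology | ER, `z = 4` | migration network (`er`, `island`, `ba`, `user`) |

The defaults satisfy every structural constraint and make an all-defector
deme non-viable (`P < E`) while a pure cooperator deme relaxes to fitness
`R > E`.  One interaction deserves emphasis: because founders and newborns
start at fitness 0 and `w = 1/2`, surviving one's first selection round
requires a round payoff `G >= 2E`.  With `E <= R/2` a newborn cooperator
survives by meeting another cooperator; thresholds above `R/2` are lethal to
every founding cooperator pair and collapse the population in one
generation.  Threshold sweeps in the tests therefore compare `E = 0.3`
against `E = 0.45`, both below `R/2`.

Founding fitness 0 is a modelling choice: it is the natural empty-history
value of the learning rule, and daughters explicitly do not inherit fitness.
Both `init_fitness` and the odd-roster rule (`unpaired_decay`: leftover
keeps its fitness, or decays toward 0) are configurable.

## Migration networks

Three generators are provided, compared at matched mean degree `z`:

* **Erdős–Rényi** (`generate_er`): each pair of demes linked independently
  with `p = z / (D - 1)`; Poisson degree distribution, finite variance.
  Graphs are used as generated — isolated demes and disconnected components
  are legitimate outcomes (an optional resampling flag enforces minimum
  degree 1).  `z < D` is required.
* **Island model** (`generate_island`): the complete graph; every degree is
  `D - 1`, zero variance — the homogeneous extreme.
* **Scale-free** (`generate_scale_free`): Barabási–Albert preferential
  attachment with attachment count `round(z / 2)`, seeded from a complete
  graph on `round(z / 2) + 1` nodes so minimum degree equals the attachment
  count; power-law degrees, the heterogeneous extreme.

The network is generated once per replicate and held fixed (quenched); no
rewiring rule is modelled.  A user edge list (0-based `u v` lines) is
accepted via `topology_spec("user", edge_list = path)`.

## Replicates, stationarity and outcome labels

A replicate is a single seeded RNG stream: network generation, founding
population, then the life cycle until one of

* `EXTINCT` — total size 0;
* `COOP_FIXED` — cooperator frequency exactly 1 (checked every generation);
* `COEXISTENCE` — a mixed state detected as stationary: the mean cooperator
  frequency over the last `W` generations differs from the mean over the
  previous `W` by at most `tol` (defaults `W = 200`, `tol = 0.01`); the
  reported `final_rho` is the last-window mean;
* `UNRESOLVED` — the horizon `max_generations` (default 5000) is reached.

The cooperator frequency is censused after selection, the end of the life
cycle.  `UNRESOLVED` runs are excluded from probability denominators and
flagged when they exceed 1% of an ensemble.  The window/tolerance/horizon
defaults are engineering choices at desk scale, exposed in `deme_params()`.

Ensemble observables follow directly: `p_coop` is the fraction of resolved
runs ending `COOP_FIXED` or `COEXISTENCE` (fixation of cooperation includes
stable coexistence), `p_coex` the fraction ending `COEXISTENCE`, and
`mean_rho` the cooperator frequency conditioned on persistence, with
`COOP_FIXED` runs contributing exactly 1.  Standard errors are binomial.

## Regime classification and the critical deme number

`classify_regime()` maps ensemble probabilities to the four phases of the
(m, D) diagram with cutoffs `eps_onset` (default 0.01) and `eps_pure`
(default 0.02), in decreasing precedence: `EXTINCTION` when
`p_coop < eps_onset`; `COEXISTENCE` when `p_coex > eps_onset` (checked
before the pure regime, so a band with certain persistence but frequent
coexistence is labelled coexistence); `PURE_COOP` when
`p_coop >= 1 - eps_pure`; otherwise `COOP_LIKELY`.  Classification demands
`n_resolved >= 1 / eps_onset`, the smallest ensemble that can resolve the
onset cutoff at all.

`phase_diagram()` holds `N` fixed across the `D` grid (so `N0 = N / D`
shrinks as structuring grows) and defines the critical deme number `D_c`
operationally as the smallest scanned `D` whose regime at the smallest
simulated migration rate is not `EXTINCTION` — an "even at minimal
migration" criterion rather than a true `m -> 0` limit.

## Randomness contract and the two engines

Every stochastic decision is expressed through two primitives on R's global
RNG stream — a one-draw uniform index in `1..k` and a Fisher–Yates shuffle —
plus a one-draw roulette wheel for proportional parenthood.  The draw order
is fixed: per deme one shuffle at the game stage; one migration-decision
uniform per individual in roster order, then one destination draw per
migrant; one tie-break draw per culling tie event; one roulette draw per
daughter.  Window means and cumulative weights are accumulated in plain
double precision.

This contract lets two independently written engines — the production C++
engine and a literal stage-by-stage R transcription (`engine = "r"` in
`run_replicate()`/`step_generations()`) — consume identical draws and
produce bitwise-identical trajectories from any seed, which the test suite
verifies over a battery of seeds and topologies.  A uniform shuffle is used
instead of base R's `sample()` precisely because `sample()`'s internal
algorithm is not reproducible through the C-level RNG API.

Numerical edge cases are fixed as follows: ties in culling are broken
uniformly (the sort-based description is silent on ties); expansion parents
are drawn from the pre-expansion survivors only (newborns have zero weight
under the default anyway, and the rule stays well-defined if
`init_fitness` is changed); when every survivor has weight 0 the parent is
drawn uniformly; negative fitness values (possible only when `S < 0`) are
clamped to weight 0 for the roulette.

## Scale of the shipped analyses, and what they do and do not show

The simulations run by the tests and by `scripts/acceptance.R` use desk-scale
study conditions: `N = 400` individuals, deme counts between 2 and 80,
ensembles of 50–200 replicates, horizons of a few thousand generations.
At this scale every qualitative phenomenon is reproducible in minutes on one
CPU: absorption-only outcomes at `m = 0`; the rise of fixation probability
with migration and the dominance of coexistence at large `m`; the decline of
the conditional cooperation level as migration intensifies; the widening of
the pure-cooperation window and the earlier onset of cooperation as `D`
grows at fixed `N`; the heterogeneity ordering of sustained cooperation
across topologies (scale-free above island) alongside statistically
indistinguishable probability curves; the shift of the onsets with the
elimination threshold; and the existence of a critical deme number at
minimal migration.

These are ensemble properties of the model itself, not calibrated
reproductions of any empirical system: probabilities at specific parameter
values shift with `N`, the payoff matrix and the cutoffs, and the
boundaries between regimes are gradual in finite ensembles (near a regime
edge the classification of a single grid point can flip between seed
blocks — `D = 4` at `m = 0.001` under the defaults is such a point).  The
synthetic founding populations are i.i.d. Bernoulli mixtures with a clean
slate of fitness; real populations with history, assortment, or
strategy-dependent dispersal are outside the model class.

## Limitations

* Interaction is panmictic inside a deme; there is no within-deme network,
  no iterated play, no memory of opponents, and no strategy imitation —
  replication is the only transmission channel.
* Migration is undirected, unweighted and quenched; no distance effects or
  rewiring.
* Stationarity detection compares two window means; extremely slow drifts
  below `tol` per window are classified as stationary, and the default
  horizon truncates pathologically long transients into `UNRESOLVED`.
* Mixed strategies, mutation and continuous traits are out of scope.
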