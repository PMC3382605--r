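# demesim

Stochastic simulation of the evolutionary prisoner's dilemma in a
deme-structured population, for researchers studying how migration and
population subdivision shape the fate of cooperation.

`N` individuals are split over `D` demes of carrying capacity `N0 = N / D`
sitting on the nodes of a migration network. Each generation applies three
stages:

1. **Game** — within every deme, individuals are randomly paired and play one
   round of the prisoner's dilemma with payoffs `T > R > P > S`
   (`2R > T + S`), then update their fitness by the learning rule
   `f' = (1 − w) f + w G`, where `G` is the round payoff. The fitness is a
   running blend of history and current payoff, bounded above by `T`.
2. **Migration** — each individual moves with probability `m` to a uniformly
   chosen neighbour deme (Erdős–Rényi random graph, Wright island model,
   Barabási–Albert scale-free network, or a user edge list), fitness
   unchanged. Empty demes can be recolonised this way.
3. **Selection** — locally in each deme: individuals with fitness below the
   elimination threshold `E` are removed; an overfull deme is culled back to
   `N0` from the least fit upward; an underfull (non-empty) deme expands to
   `N0` by fitness-proportional replication, daughters inheriting the
   parent's strategy but not its fitness.

Replicates run until extinction, fixation of cooperation (cooperator
frequency `ρ = 1`), a detected stationary coexistence state (`0 < ρ < 1`),
or a horizon. Ensembles of replicates estimate the fixation probability
`p_coop`, the coexistence probability `p_coex`, and the cooperation level
conditioned on persistence; grids over `(m, D)` map the four regimes
(extinction, cooperation likely, pure cooperation, coexistence) and the
critical deme number `D_c` above which cooperation is likely even at minimal
migration.

Everything user-facing is tidy: analysis functions return tibbles, fitted
objects have `tidy()`/`glance()` methods and `autoplot()` ggplot2 methods.
A C++ engine does the heavy lifting; a pure-R reference engine
(`engine = "r"`) reproduces its trajectories bit for bit from any seed.

## Worked example

```r
library(demesim)

params <- deme_params(N = 400, D = 20, m = 0.5)   # ER network, z = 4
rep <- run_replicate(params, seed = 1)
glance(rep)
#> # A tibble: 1 × 4
#>    seed outcome     final_rho generations_run
#>   <int> <chr>           <dbl>           <int>
#> 1     1 COEXISTENCE     0.326             400
```

At `m = 0.5` this replicate settles into stationary coexistence: after 400
generations cooperators stabilise at about 33% of the population —
cooperation persists, but heavy mixing lets defectors survive by moving
between demes.

```r
sw <- sweep_migration(params, m_grid = c(0.001, 0.01, 0.1, 0.5, 0.9),
                      n_runs = 50, base_seed = 1)
dplyr::select(tibble::as_tibble(sw), m, p_coop, p_coex, mean_rho)
#> # A tibble: 5 × 4
#>       m p_coop p_coex mean_rho
#>   <dbl>  <dbl>  <dbl>    <dbl>
#> 1 0.001   0.28   0       1
#> 2 0.01    0.84   0.2     0.995
#> 3 0.1     0.98   0.98    0.553
#> 4 0.5     0.72   0.72    0.364
#> 5 0.9     0.66   0.66    0.325
```

Reading the sweep: at near-zero migration demes are isolated and cooperation
rarely persists (`p_coop = 0.28`), but when it does, it dominates completely
(`mean_rho = 1`, no coexistence). Increasing migration first boosts fixation
(`p_coop` rises to ~1 by `m = 0.1`) and then opens the coexistence phase
(`p_coex` jumps to match `p_coop`), within which the sustained cooperation
level falls as mixing intensifies (0.55 → 0.33). `autoplot(sw)` draws the
curves; `phase_diagram()`, `compare_topologies()` and `sweep_threshold()`
run the corresponding grid analyses.

A thin command-line driver ships in `inst/cli/demesim.R`:

```sh
Rscript inst/cli/demesim.R sweep --config config.yaml --runs 100 --out-dir out/
```

with subcommands `simulate | sweep | phase | topology | threshold`, a
YAML/JSON config mirroring the `deme_params()` arguments, and flags
overriding the file.

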