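# fbagames

Evolutionary game theory on constraint-based metabolic models, in R.

Microbial communities are shaped by leaked metabolites: a strain that sheds
amino acids or hydrolysis products feeds its neighbors, including mutants
that have lost the corresponding pathway.  `fbagames` computes the payoffs
of these interactions from metabolism itself — no phenomenological fitness
assumptions — and then asks the game-theoretic questions: which strain
combinations are equilibria, which are evolutionarily stable, and how do
the answers change with leakiness and production cost?

The pipeline:

1. **Fitness from stoichiometry** — flux balance analysis (FBA): maximize
   the biomass flux `v_biomass` subject to steady-state mass balance
   `Σ_j s_ij v_j = 0` and flux bounds `LB_j ≤ v_j ≤ UB_j`.
2. **Genotypes as constraints** — gene deletions (`v_j = 0`), forced
   metabolite leakage (`v_EX_i ≥ e_i`), and uptake of partner-supplied
   goods (`v_EX_i ≥ −u_i`).
3. **Payoff tensors** — one independent FBA solve per (genotype, partner
   profile), each assuming availability of what the partners leak;
   infeasible or sub-viable problems score a negative death rate.
4. **Nash equilibria** — all pure-strategy equilibria of the n-player game
   at once, via an indicator integer linear program (`a¹_pq ≥
   max_p′{a¹_p′q}·w_pq + LB₁(1−w_pq)`, maximize `Σ w`), with an exhaustive
   brute-force oracle as an independent cross-check.
5. **Evolutionary dynamics** — the replicator equation
   `dx_k/dt = (f_k(x) − φ(x))x_k` with higher-order interaction terms,
   in silico invasion experiments, and selection coefficients.
6. **Landscapes** — two-parameter scans (production cost × capture
   efficiency, or leakiness × leakiness) classified into Prisoner's
   Dilemma / Snowdrift / Mutually Beneficial phases, with sustainable-
   leakiness and cross-feeding-only region masks.

Small synthetic fixture networks (an invertase-style public-good system
and a two-amino-acid cross-feeding system with optional pleiotropic or
epistatic pathway coupling) make the whole pipeline runnable and testable
without any external model downloads.

## Worked example

```r
library(fbagames)

# Producer (WT) vs non-producer (MT) on sucrose: cost 0.75 ATP/sucrose,
# 75% of hydrolysis products lost to the commons, trace glucose medium.
fx <- make_sucrose_fixture(atp_cost = 0.75, leak_fraction = 0.75,
                           glucose_medium = 2)
game <- build_payoff_tensor(fx$model, fx$genotypes)
game$payoffs[[1]]
#>          WT       MT
#> WT 10.25000 2.166667
#> MT 11.33333 1.333333

find_nash_ilp(game)
#> <nash_result> 2 pure-strategy Nash equilibria:
#>  player1 player2              payoff
#>       MT      WT 11.333333, 2.166667
#>       WT      MT 2.166667, 11.333333

classify_game(find_nash_ilp(game), game, "WT", "MT")$label
#> [1] "snowdrift"

inv <- invade(game, residents = "WT", invaders = "MT", t_max = 3000,
              n_steps = 1500)
round(inv$equilibrium, 4)
#>     WT     MT
#> 0.4348 0.5652
```

Payoffs are growth rates (1/h) from the genotype-specific FBA problems.
Here the producer facing itself grows at 10.25/h, a cheater exploiting a
producer at 11.33/h, and an exploited producer at 2.17/h — the
anti-coordination ordering of a snowdrift game, so producer and cheater
coexist, and the replicator dynamics settle at ~43% producers regardless
of who invades whom.

The four-genotype amino-acid system works the same way:

```r
aa <- make_two_amino_acid_fixture()        # genotypes 11, 10, 01, 00
gs <- aa$genotypes(2.5, 2.5)               # leak 2.5 mmol/gDW/h each
t4 <- build_payoff_tensor(aa$model, gs)
find_nash_ilp(t4)
#> <nash_result> 4 pure-strategy Nash equilibria:
#>  player1 player2        payoff
#>       00      11 2.5, 1.666667
#>       01      10      2.5, 2.5
#>       10      01      2.5, 2.5
#>       11      00 1.666667, 2.5
```

— the coexistence of unidirectional dependency [00, 11] and cross-feeding
[01, 10] that characterizes the sustainable-leakiness ("green") region.
`scan_landscape()` maps such results over full parameter grids, and
`sustainable_region()` extracts where the full producer still grows.

A thin command-line wrapper (`inst/scripts/fbagames-cli.R`) exposes the
stages as subcommands: `fba`, `payoff`, `nash`, `dynamics`, `scan`,
`fixture`.

## Package layout

- `R/lp.R` — dense two-phase simplex (Bland's rule) used by the FBA core
- `R/model.R`, `R/fba.R` — model container, JSON schema, SBML import, FBA
- `R/genotype.R` — deletions, leakage, uptake, maximum sustainable leakiness
- `R/payoff.R` — pairwise payoffs and n-player payoff tensors
- `R/nash.R` — NashEq ILP enumeration + brute-force oracle
- `R/dynamics.R` — replicator dynamics, invasions, selection coefficients
- `R/landscape.R` — grid scans, game classification, region masks
- `R/fixtures.R` — synthetic study systems
- `R/pipeline.R` — config-driven end-to-end runs
- `vignettes/metabolic-games.Rmd` — the model, assumptions, and numerical
  choices in detail
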