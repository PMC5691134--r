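---
title: "Metabolic games: from flux balance payoffs to evolutionarily stable communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic games: from flux balance payoffs to evolutionarily stable communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbagames)
```

## The model

Microbes that leak metabolites create public goods: a strain that sheds an
amino acid or a hydrolysis product feeds any neighbor able to take it up,
including mutants that have abandoned the corresponding biosynthetic
pathway.  Whether the producer persists, is displaced by cheaters, or locks
into obligate cross-feeding is a game-theoretic question -- and the payoffs
of that game can be computed from metabolism itself rather than assumed.

`fbagames` builds that chain end to end:

1. **Fitness from stoichiometry.**  For a strain with metabolic network
   stoichiometry $s_{ij}$ (metabolites $i \in I$, reactions $j \in J$),
   flux balance analysis (FBA) predicts the growth rate as the optimum of a
   linear program:
   $$\max v_{\mathrm{biomass}} \quad \text{s.t.} \quad
     \sum_{j} s_{ij} v_j = 0 \;\; \forall i, \qquad
     \mathrm{LB}_j \le v_j \le \mathrm{UB}_j \;\; \forall j.$$
2. **Genotypes as constraints.**  A genotype adds three constraint types:
   deletions $v_j = 0$ for $j \in J^{\mathrm{mutation}}$; forced net export
   $v_{\mathrm{EX}_i} \ge e_i$ for each leaky metabolite $i$; and uptake
   allowances $v_{\mathrm{EX}_i} \ge -u_i$ for metabolites supplied by
   partners.  Exchange fluxes are positive for secretion and negative for
   uptake.
3. **Payoffs.**  For a pair (or larger group) of genotypes, each member's
   FBA problem is solved *independently*, assuming availability of
   everything its partners shed ($u_i$ = the sum of the partners' declared
   leak fluxes).  The payoff is the optimal biomass flux, or a negative
   *death rate* when the problem is infeasible or growth falls below the
   viability threshold.
4. **Equilibria.**  All pure-strategy Nash equilibria of the resulting
   payoff tensor are enumerated at once by an indicator integer linear
   program, cross-checked against exhaustive search.
5. **Dynamics.**  The replicator equation, extended with higher-order
   interaction terms, turns the same tensor into frequency dynamics,
   invasion experiments and selection coefficients.

## Worked example

```{r example}
fx <- make_sucrose_fixture(atp_cost = 0.75, leak_fraction = 0.75,
                           glucose_medium = 2)
game <- build_payoff_tensor(fx$model, fx$genotypes)
game$payoffs[[1]]
nash <- find_nash_ilp(game)
nash
classify_game(nash, game, cooperator = "WT", defector = "MT")$label
```

At this production cost and capture efficiency the producer and the
non-producer coexist (a snowdrift game); the replicator dynamics converge
to the same mixture from either invasion direction:

```{r invade}
up <- invade(game, residents = "WT", invaders = "MT", t_max = 3000,
             n_steps = 1500)
round(up$equilibrium, 4)
```

## Constraint semantics: committed leaks, shed goods, and availability

The forced-export constraint $v_{\mathrm{EX}_i} \ge e_i$ and the uptake
allowance $v_{\mathrm{EX}_i} \ge -u_i$ are both *lower bounds on the same
exchange flux*.  When a genotype leaks metabolite $i$, the forced export
dominates ($\max(e_i, -u_i) = e_i$): a committed leak is never offset by
what partners supply.  This is deliberate.  Leakiness here is a phenotype
the strain cannot switch off, and it is exactly what makes high leakiness
unsustainable for the full producer -- the boundary that separates the
"sustainable leakiness region" from the region where only cross-feeders
survive.

Some public goods are not exported through a forced exchange bound but shed
*structurally*, through reaction stoichiometry.  In the sucrose system the
invertase reaction itself splits its products: a fraction $1-e$ is captured
privately, a fraction $e$ leaves as a diffusible pool.  The `provides`
field of a genotype declares such structurally shed fluxes: they feed the
partners' availability exactly like forced leaks, but impose no extra
constraint on the producer (the stoichiometry already accounts for the
loss).  The sucrose fixture splits the commons into an outbound pool
(whose forced export commits the producer to full hydrolysis) and an
inbound pool that partners may draw on, so that each independent FBA
problem counts every molecule exactly once.

Availability aggregates as the plain sum over partners, $u_i = \sum_k
e_i^{(k)}$.  An alternative `aggregation = "split"` divides each partner's
leak evenly among its co-players; we default to the sum as the simplest
reading of "each assumes availability of what the other leaks", and expose
the choice because nothing in the independence approximation fixes it.

## The fixtures: what they emulate, and what they do not

No genome-scale reconstruction ships with this package.  Instead, two toy
networks with small integer stoichiometries reproduce the *structure* of
the study systems, so that every payoff in the test suite can be checked
against a hand-solvable linear program.

**Sucrose public good** (`make_sucrose_fixture`).  Sucrose (uptake bound
10 mmol/gDW/h) is hydrolyzed at an ATP cost $x$ per sucrose into two
hexose equivalents, of which a fraction $e$ diffuses away.  Catabolism has
a high-yield route (2 ATP per hexose) capped at 6 mmol/gDW/h and an
unbounded low-yield overflow route (1 ATP per hexose); biomass consumes
one hexose and one ATP.  The saturation makes growth concave but strictly
increasing in sugar supply -- the feature that separates a producer rich in
private sugar from a cheater living off the commons, and without which the
Prisoner's Dilemma region degenerates into payoff ties.  The default
scanning medium includes 2 mmol/gDW/h of free glucose: a strictly
sucrose-only medium pins the cheater pair exactly at the death rate,
producing tied, degenerate Nash sets at every collapse cell; the trace
sugar keeps the mutant weakly viable so the classified phases are
well-defined.  Raising `glucose_medium` (e.g. to 10) models glucose
supplementation, which weakly expands the Prisoner's Dilemma region, as
the package's scans confirm.

**Two leaky amino acids** (`make_two_amino_acid_fixture`).  A carbon
source yields a biosynthetic precursor plus ATP; amino acids A and B cost
one precursor plus `cost_A`/`cost_B` ATP each; biomass requires A, B,
precursor and ATP in equal amounts.  The genotypes `11`, `10`, `01`, `00`
arise by deleting the synthesis genes, each partial producer leaking the
amino acid it still makes.  Leakiness axes are expressed as percentages of
the full producer's maximal sustainable leak flux (found by bisection),
mirroring how such scans are usually reported.  With default costs the
landscape shows the canonical progression: at moderate leakiness both the
unidirectional dependency [00, 11] and cross-feeding [01, 10] are Nash
("green" region); past the producer's sustainability boundary
cross-feeding is the only viable association ("red" region), and the two
regions touch.

Two pathway-coupling variants probe how core biochemistry reshapes the
landscape:

- `coupling = "pleiotropy"` routes A synthesis through the committed
  intermediate of B's pathway.  A strain that lost B's gene therefore
  cannot make A either -- it behaves like a double auxotroph -- and
  imported B cannot re-enter the committed pool (the exchanged form and
  the biosynthetic intermediate are distinct metabolites).  Cross-feeding
  is structurally impossible at every grid cell.
- `coupling = "epistasis"` makes A's pathway co-produce a side metabolite
  required for biomass, with an expensive salvage route (2 precursor +
  `salvage_cost` ATP) as the only alternative source.  Strains lacking A's
  pathway carry the salvage burden, so a retained pathway is worth more
  than its naive ATP cost: in part of the sustainable region the double
  auxotroph is *less* fit facing the full producer than the partial
  producer `10`, which removes [00, 11] from the Nash set while [01, 10]
  remains.  This is a directional coupling, as in real amino-acid pairs
  whose products are biosynthetically linked.

What passing these scans does *not* show: the toy networks have one carbon
source, no redundancy, no maintenance requirement and integer yields, so
quantitative boundaries (where exactly the snowdrift band lies, how wide
the green region is) carry no information about any real organism.  The
claims the tests make are structural -- which phases exist, how they are
ordered along the axes, which couplings forbid which equilibria.

## Nash enumeration

For every strategy profile $pq$ a binary indicator $w_{pq}$ is constrained
by
$$a^1_{pq} \ge \Big(\max_{p'} a^1_{p'q}\Big) w_{pq} + \mathrm{LB}_1 (1 - w_{pq}),$$
and its analogues for the other players, with $\mathrm{LB}_s$ set
automatically to $\min_s a - 1 - |\min_s a|$, strictly below the player's
worst payoff so the constraint is slack at $w = 0$.  Maximizing $\sum w$
then sets each indicator to 1 exactly when its profile survives every
unilateral deviation (weak inequality; ties produce multiple equilibria,
which are reported as such).  Because each binary appears only in its own
constraints, the branch-and-bound tree collapses at the root and the ILP is
solved to provable global optimality with zero gap; the package constructs
the full constraint system and exploits that separability directly.  Note
that $w \equiv 0$ is always feasible, so an empty equilibrium set appears
as an optimum of zero, not as infeasibility, and is reported as "no
pure-strategy Nash equilibrium".  `brute_force_nash` re-derives the same
sets by exhaustive deviation checks and the test suite holds the two
routes identical over hundreds of random tensors of 2-4 players with 2-5
strategies each.

Payoff ties are compared with a tolerance of `1e-9` (`tie_tol`), below any
meaningful growth-rate difference but above LP round-off.

## Replicator dynamics

Frequencies $x_k$ evolve as $\dot x_k = (f_k(x) - \phi(x)) x_k$ with
$f_k$ the expected payoff against the community (a polynomial in $x$ for
higher-order tensors) and $\phi = \sum_k f_k x_k$ the mean fitness.
Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`;
states are renormalized only when simplex drift exceeds $10^{-8}$, and an
equilibrium is declared when $\|\dot x\|_\infty$ stays below `tol`
(default $10^{-7}$) across the trailing ten reported states.  Death-rate
payoffs are negative, so non-viable genotypes decay exponentially.

Invasion experiments (`invade`) first equilibrate the residents among
themselves, then rescale to make room for the invaders at a total
frequency of 1% by default (the value is configurable; published
experiments rarely state it, and the equilibria we assert are insensitive
to it).  Three presets cover the canonical four-genotype scenarios:
simultaneous triple invasion of the full producer, the two-step loss of
prototrophy (10 and 00 invading an equilibrated 11 + 01 community), and
cross-feeders invading the full producer.

The selection coefficient is computed as
$s = (f_{\mathrm{MT}} - f_{\mathrm{WT}})/\phi$ at the community state
implied by the mutant/resident ratio.  The literature uses several
near-equivalent definitions; this one was chosen because it reduces to the
familiar relative-fitness excess in the rare-mutant limit and crosses zero
exactly at the interior replicator equilibrium, both of which the tests
verify.

## Numerical choices

- **LP backend.**  FBA problems are solved by the package's dense
  two-phase simplex with Bland's anti-cycling rule (pivot tolerance
  $10^{-9}$).  The networks this package targets are tiny (tens of
  reactions), where robustness matters more than speed; the solver is
  validated against an independent LP implementation on randomized
  degenerate problems in the test suite, and optimal flux vectors are
  re-checked for mass balance to $10^{-6}$ after every solve.  Unbounded
  problems are reported as such rather than clamped -- in a metabolic
  model an unbounded biomass flux means a missing exchange bound.
- **Viability threshold.**  Growth below $10^{-6}\,h^{-1}$ counts as
  non-viable and maps to the death rate, making collapse explicit instead
  of leaving near-zero payoffs to float numerically.
- **Death rate.**  Default $-0.05\,h^{-1}$, configurable.  Its magnitude
  only scales how fast non-viable strains decay under the replicator
  equation; Nash membership among viable profiles is unaffected, which the
  payoff-band test pins down.
- **Bisection.**  `max_sustainable_leakiness` brackets with a
  secretion-capacity LP (an upper bound by construction) and bisects to an
  absolute tolerance of $10^{-4}$ times the bracket width by default; the
  returned value is feasible and the value two tolerances higher is not.
- **Gene mapping.**  Gene deletion uses a plain many-to-many gene-to-
  reaction map: a reaction is removed when any deleted gene maps to it.
  Boolean gene-protein-reaction logic is out of scope; where several
  deletions could induce the same auxotrophy one is chosen when the
  fixture is built.

## Problem sizes

The shipped analyses are sized for interactive use: the sucrose landscape
runs on a 9 x 10 (cost x capture-efficiency) grid, the amino-acid
landscapes on 11 x 11 leakiness grids (the 21-level, 441-cell grid of
`leakiness_grid()` remains the default for full-resolution scans), and the
Nash cross-validation draws 200 random tensors up to 4 players x 5
strategies.  Each landscape cell costs at most $K^2$ cached LP solves, so
a full 441-cell scan of the four-genotype system stays well under a
minute.

## Limitations

- Payoffs come from independent steady-state FBA solves: no metabolite
  pool dynamics, no shared-medium depletion, no population-size feedback
  on the environment.  Communities where growth changes the medium faster
  than it equilibrates need dynamic community FBA instead.
- Only pure-strategy Nash equilibria are enumerated; games whose only
  equilibria are mixed report an empty set.
- The replicator equation assumes effectively constant population size;
  extinction here means frequency, not census, decline.
- SBML import is best-effort (FBC bounds and objective when present,
  defaults otherwise) and intended for small curated models; the JSON
  schema is the canonical format.
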