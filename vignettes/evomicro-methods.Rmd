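---
title: "Model and methods behind evomicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind evomicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

evomicro simulates eco-evolutionary dynamics of digital microbes whose
metabolic networks are free to evolve. This vignette documents the model,
every numeric choice the package makes where the published description of
this model class leaves freedom, and what the synthetic conditions do and
do not show about real microbial communities.

## The chemical universe

The reference universe (`load_reference_universe()`) holds nine metabolites
— a single externally supplied resource `R`, two non-substitutable building
blocks `B1` and `B2`, an energy carrier `E`, and five intermediates `M1..M5`
— connected by 43 conversion reactions plus an importer and exporter for
every non-energy metabolite (59 reactions in total). Each metabolite has a
per-step environmental diffusion rate, degradation rate, toxicity threshold
and (for `R` only) an influx rate. The chemistry is deliberately not
mass-balanced: degradations release energy units without a conservation
constraint, which is part of the model design, not an implementation
shortcut.

The canonical reaction ordering — conversions in the published column-major
table order, then importers in symbol order (`B1, B2, M1..M5, R`), then
exporters — defines the 59-bit metabolic genotype used for clade tracking,
gene-frequency matrices and topology classification. Any stable order would
serve; this one is fixed in the fixture file and round-trips through all
serializations.

`generate_universe()` builds random universes from the same structural
families (single-substrate energy-yielding degradations `A -> B + k E`,
two-substrate syntheses, condensations `2 A -> B`) under rejection sampling
until both building blocks and energy are reachable from the resource.

## Cell physiology

Each cell couples, in one ODE system per time step: internal metabolite
concentrations, per-gene protein concentrations, a biomass budget `B`, cell
volume, a toxicity accumulator, and the external pools of its lattice site.

* **Transport.** `v = vmax * [T] * [S]/([S]+K_S) * [E]/([E]+K_E)`, with
  `[S]` external for importers and internal for exporters. One unit of `E`
  is consumed per unit transported; the published description does not
  print a stoichiometry, and 1:1 is the simplest choice.
* **Catalysis.** `v = vmax * [enzyme] * prod[R]/prod([R]+K)` with a single
  shared Michaelis constant per gene, following the printed rate law, which
  takes each *distinct* reactant once. Whether a doubled reactant (as in
  `2 M2 -> B1`) should enter squared is genuinely ambiguous; the package
  implements the plain product and exposes `stoich_powers = TRUE` in
  `dynamics_params()` for the alternative.
* **Production.** Building blocks convert to budget at
  `[B1][B2]/(1 + |B1-B2|)`, consuming each building block at the production
  rate (1:1 with the budget produced). The penalty term favours
  building-block homeostasis.
* **Budget scaling.** All spending (growth, expression) is scaled by
  `B/(B + B_pop)` where `B_pop` is an exponential moving average (horizon
  100 steps) of mean per-cell production. The average is bounded below by
  `b_pop_floor = 2e-4` — about half the production rate of the ancestral
  cell state. This floor gives the otherwise purely relative scaling an
  absolute viability scale: a community whose production collapses loses
  spending power, shrinks and starves. Without it, a starving population
  idles forever at near-maximal volume because the scaling reference decays
  exactly as fast as its budget, and lineage-removal assays would never
  terminate in extinction.
* **Volume.** Logistic growth `g*Vol*(1 - Vol/Vol_max)*B_scaling` minus
  shrinkage `s_shrink*Vol`. With the default `Vol_max = 1` this is exactly
  the printed growth form.
* **Dilution.** Every internal species is diluted at `(dVol/dt)/Vol`, the
  signed relative growth rate, so internal amounts `conc * Vol` are exactly
  invariant under pure volume change (shrinking concentrates).
* **Toxicity and death.** `e_tox` accumulates
  `sum_m max(0, ([m]-tox_m)/tox_m)` along the lifetime; the per-step death
  probability is `e_tox/(s_tox+e_tox)*(1-r) + r` with intrinsic rate
  `r = 0.03`. Survivors keep their toxic load; offspring start clean.

### Unprinted constants

The model description fixes `r = 0.03`, the mutation rates and the
kinetic-parameter range `[0.01, 8]`, but not the remaining physiological
constants. The package's defaults were chosen once, such that a randomly
parameterised viable ancestor grows to division volume within a few steps
and the ancestral population persists indefinitely:

| parameter | default | meaning |
|---|---|---|
| `g` | 1.0 | volume growth rate |
| `s_shrink` | 0.01 | volume decay |
| `vol_max`, `vol_divide`, `vol_starve` | 1.0, 0.5, 0.05 | size thresholds |
| `s_tox` | 1.0 | toxicity half-effect scale |
| `expr_cost` | 0.02 | budget cost per unit promoter strength |
| `b_deg`, `prot_deg` | 0.01, 0.1 | budget and protein decay |
| `b_pop_window`, `b_pop_floor` | 100, 2e-4 | production-average horizon, floor |
| `mdiff_mult` | 1.0 | passive membrane diffusion multiplier |

Passive membrane diffusion reuses the per-metabolite environmental
diffusion rates (`flux = diffusion_m * ([ext] - [int])`), as the model's
schematic shows passive exchange across the membrane; the multiplier
exposes it for sensitivity work. `expr_cost` is the baseline of the
protein-cost axis that the original study swept over an order of magnitude
in both directions; its absolute value is not printed anywhere, and the
default produces visible but not crushing expression costs (genomes grow
to ~20-25 genes over 2e4 steps on a small grid).

Initial conditions emulate inoculating fresh medium: external pools start
empty (the resource accumulates from influx at 0.002 per site per step),
and cells start at volume 0.4 with budget 1 and small sub-threshold
internal stores (`R = 0.02, E = 0.01, B1 = B2 = 0.02`). Starting pools at
the resource steady state instead (`init_pools = "steady"`) makes naive
ancestors gorge on resource and die of toxicity, which is also why the
stores start below every toxicity threshold.

## Units and conservation

Pools are amounts per site with site volume 1; internal state is
concentration in the cell volume. Membrane rates are written as
concentration changes inside the cell, and the pool side is scaled by the
cell volume, so the transported *amount* is exactly conserved; `lyse()`
returns `concentration * volume` to the site on death. With degradation
disabled, pool loss equals the gain in internal amount to integrator
tolerance (this is a unit test).

## Numerical integration

Each occupied site's coupled cell+pool system is advanced one time step
(`dt = 1`) with relative tolerance 1e-6 and absolute tolerance 1e-9 by
default, then grid-level influx, degradation and diffusion apply (operator
splitting; the splitting error is second order in the step and irrelevant
at the model's rates). Concentrations are clamped at zero after each
accepted substep. For long evolutionary campaigns the package's own
experiments relax the tolerances to `rtol = 1e-4`, `atol = 1e-7` (set via
`dynamics_params()`): the integrator is error-limited, so this cuts the
substep count several-fold, while the per-step ODE error it admits is
orders of magnitude below the stochastic demographic noise (3% death
lottery per step) that actually drives the eco-evolutionary dynamics.
Single-cell operations and all invariant tests keep the tight defaults.

The default integrator (`integrator = "auto"`) is a linearly implicit
RODAS3 Rosenbrock method (L-stable, stiffly accurate, order 3 with an
embedded order-2 error estimate). Stiff capability matters because
evolution freely combines the smallest Michaelis constant (0.01) with high
expression levels, producing kinetic rates three orders of magnitude above
the step scale. The linear algebra exploits the system's structure: the
protein block of the Jacobian is diagonal and the protein columns are
analytic (every rate is linear in its protein), so a Schur complement
reduces each solve to a dense core+pool system whose size is independent
of genome length; core and pool columns come from forward differences,
aged across accepted substeps, and each cell's substep size is
warm-started from the previous time step. An explicit Cash-Karp
Runge-Kutta 4(5) (`integrator = "rk45"`) is retained as a rescue path and
as a cross-check. Both methods agree with each other and with an
independent `deSolve::lsoda` solution of the pure-R right-hand side
(`cell_odes()`) to ~5e-4 absolute on test trajectories (mostly ~1e-5
relative); the toxicity accumulator, whose integrand is kinked and feeds
back into nothing within a step, is accurate to ~5e-3 under the default
method (the explicit method resolves it to 2e-4). The pure-R path is kept
solely as that oracle.

A cell whose integration fails (non-finite state or substep exhaustion) is
flagged and dies deterministically in the following death phase; this has
not been observed in any test run but keeps a pathological cell from
aborting a whole simulation.

## The scheduler

A time step applies, in order: (1) ODE integration of all occupied sites;
(2) environment influx, degradation, diffusion (or well-mixed averaging:
all pools replaced by the global per-metabolite mean, which conserves
totals); (3) stochastic death with lysis (starving and failed cells die
deterministically); (4) lottery reproduction over empty sites in shuffled
order — Moore neighbours at or above `vol_divide` compete with weights
equal to their instantaneous production, against a "no reproduction"
pseudo-entrant whose weight is the current `B_pop` (the dynamic scaling of
reproduction chance with community productivity); (5) HGT and gene
discovery per cell; (6) marker renewal; (7) recording. The published
description does not print its exact sub-step order; order sensitivity is
a known caveat of all such schedulers.

Reproduction halves the volume between parent and offspring, leaves all
concentrations unchanged, replicates the genome with mutations, and resets
the offspring's toxicity and lifetime. When a stretch mutation changes the
gene count, offspring protein concentrations are re-initialised from
promoter strengths rather than mapped gene-by-gene through the
rearrangement; at the default rates (one stretch event per ~250
replications) the approximation touches a negligible fraction of births.
Metabolite and protein diffusion to offspring are otherwise exact copies.

Randomness is organised as named per-phase streams (initialisation, death,
lottery, mutation, HGT, shuffling) derived from one master seed, so
disabling one stochastic process (e.g. mutations in a dependency assay)
does not shift any other stream. Runs are reproducible bit-for-bit given
a config and seed; snapshots (JSON) restore the streams and resume within
double-precision printing accuracy (~1e-15 relative), which keeps
trajectories identical for hundreds of steps.

## Mutation operators

Stretch duplication, deletion, inversion and translocation fire
independently per replication at probability 0.001 each, in that fixed
order, with geometric stretch lengths (`P = 0.3`, truncated at the genome
end and the start position uniform). Point mutations hit each gene at
0.02 per replication, pick one evolvable parameter uniformly (promoter,
K_S, v_max, plus K_E and the direction flag for transporters), multiply
numeric parameters by a log-uniform factor in `[1/2, 2]` and reflect in
log space into `[0.01, 8]`; the direction flag flips and retargets the
paired transport reaction. The multiplicative proposal is the package's
choice — only the range is published — and gives scale-free local tuning
consistent with the continuous parameter adaptation the model class is
built to show. Gene discovery (0.0001) and HGT from a uniformly chosen
occupied Moore neighbour (0.0005) are per-cell per-step events; acquired
genes start at zero protein concentration.

## Analyses

* **Metabolic genotype and clades.** The 59-bit presence/absence vector,
  invariant to copy number and parameters. Every genotype-changing birth,
  HGT or discovery event founds a new clade whose parent is the cell's
  previous clade; abundances are recorded at the configured cadence.
* **Muller tables.** Abundances subsampled every 500 steps; clades that
  never reach 5% of the maximum population size are folded into their
  nearest surviving ancestor (or a synthetic `"ancestral"` identity), and
  the output is the edge + population table pair in the stacked-nesting
  convention used by Muller-plot tooling. Population size is conserved at
  every sampled step by construction.
* **Topology.** A conversion that yields `E` is classified by what it
  degrades: the resource (`resource_energy`, the cross-feeding-associated
  topology), a building block (`bb_energy`, autonomy-associated), or
  neither (`none`, e.g. intermediate-fed energy reactions). A community is
  called on the reactions present at frequency >= 0.05; both classes
  present give `hybrid`.
* **Dependency assays.** `dependency_test()` removes every cell of one
  renewing-marker lineage without lysis (their internal metabolites leave
  the world), zeroes all mutation, discovery and HGT rates, freezes marker
  renewal, and runs at most 2000 steps, measuring community production
  (the sum of cell production rates) just before removal and 1500 steps
  after. The 2000/1500 pair keeps both published conventions: the cap and
  the measurement time.
* **PCA.** `prcomp` on centred gene-frequency or relative-proteome
  matrices with a deterministic sign convention (largest-magnitude loading
  positive).

## Engineered fixtures

`make_fixture_crossfeeders()` builds a two-strain obligate pair: each
strain imports `R`, degrades it for energy (`R -> M2 + 5 E`), condenses
`2 M2` into one building block, exports that block and imports the other.
Neither closes the network alone (a viability check in the tests); either
removal drives the partner extinct within a few hundred steps.
`make_fixture_autonomous()` builds the major/minor structure of evolved
cross-feeding communities: a nearly autonomous major (strong B2
synthesis, a deliberately weak backup B1 pathway, B1 import and B2
export) and a B1-specialist minor that depends on the major for B2. The
pair coexists with oscillating lineage ratios; removing the major kills
the minor, while removing the minor leaves the major alive but stripped
of its B1 subsidy and of the minor's above-average production, so the
survivor's community production drops — the directional signature of
facultative cross-feeding. Under full mutation the engineered division of
labour erodes within a few hundred steps (selection strengthens the
major's backup pathway), so lineage-removal assays on evolved snapshots
sample early checkpoints. The parameters are hand-set, and the fixtures
are synthetic constructions for assay semantics — they are not evolved
communities, and their coexistence is maintained by frequency-dependent
building-block exchange, not by evolved niche refinement.

## Problem sizes and what the tests show

The packaged test suite runs the full physiology but at reduced scale:
lattices of 5x5 to 16x16 for unit and assay tests, and one 15x15 /
20 000-step evolution run, the package's standing scaled-down experiment.
At that scale the qualitative phenomena reproduce — populations persist,
genomes and community production grow, a single dedicated energy reaction
sweeps to fixation and the topology classifier returns a definite class —
but deep-time phenomena (strategy switching, the full cross-feeding /
autonomy dichotomy across replicates, well-mixed invasion dynamics) need
the original scale (45x45, 1e6 steps, 60 replicates), which the package
supports but does not test. Dependency assays on *evolved* cross-feeding
communities are approximated by evolving the engineered pair under full
mutation for a few thousand steps and assaying both lineages at several
time points. The synthetic generator emulates the study conditions
(2025-cell viable random ancestors, constant resource influx, fixed
mutation rates); it does not emulate features of real microbial data such
as measurement noise, phylogenetic signal in parameters, or non-constant
environments, so passing tests demonstrate internal consistency of the
model, not fit to any biological dataset.
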