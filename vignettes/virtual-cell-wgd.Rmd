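---
title: "Virtual-cell evolution and post-WGD genome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-cell evolution and post-WGD genome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcellevo)
```

# The model

`vcellevo` simulates populations of *virtual cells*: agents whose circular
genomes encode a small regulated metabolism, selected for homeostasis under
a fluctuating external resource, and mutated at both the gene and the
genome scale — including whole-genome duplication (WGD). The package's
purpose is the analysis of what happens *after* a WGD: which duplicates
(ohnologs) are retained, how that compares to selection-free null models,
and how retention relates to regulatory connectivity.

## Genes, promoters and the regulatory network

A genome is an ordered circular list of genes of three categories:

* **transcription factors (TFs)** sense an intracellular ligand — the
  resource A or the energy carrier X — and regulate genes;
* **enzymes** either catabolise A into X (`cat`) or consume A and X in an
  anabolic reaction that acts as a sink (`ana`);
* **pumps** import external A at an energy cost paid in X.

Each gene has a promoter: an operator motif plus a basal expression rate.
Motifs are discrete strings of length `L` over an alphabet of size `S`
(defaults `L = 12`, `S = 2`, both configurable). A TF regulates exactly the
genes whose operator is *identical* to its binding motif. We deliberately use
exact matching with no mismatch tolerance: partial matching would let TFs
retain some targets while losing others (sub-function splitting), which is a
different model. With discrete all-or-none interactions, binding-site
divergence is the 0/1 quantity reported by `bs_conservation()`, and
regulatory rewiring happens in discrete jumps. Self-regulation is permitted
(feedback is how homeostasis is achieved), and each gene carries one
operator; multi-operator promoters are out of scope.

Because random length-12 binary motifs almost never coincide, the random
founding genomes built by `random_genome()` draw operators and binding
motifs from a small shared vocabulary of motif "words" (default 8 per
genome). This gives founders a connected starting network that evolution
can prune and rewire one symbol flip at a time; with fully independent
random motifs the founders would have essentially no regulation at all and
the selected wiring would have to be discovered de novo through a
six-mutation valley.

## Intracellular dynamics

The cell state is `(A_int, X_int, P_1..P_n)`. Fluxes are saturating:

* catabolic: `v = k_cat * P * A/(K_A + A)`, yielding `conversion_rate * v`
  of X;
* anabolic: `v = k_cat * P * A/(K_A + A) * X/(K_X + X)`, consuming A and X;
* pump: `v = k_cat * P * A_ext/(K_Aext + A_ext) * X/(K_X + X)`, importing A
  and consuming `cost * v` of X;
* diffusion: `permeability * (A_ext - A_int)`.

Ligand binding of TFs and TF-operator binding are fast and treated at quasi
steady state. A regulator `t` of gene `g` contributes
`w_t = occ_t * (b_t * eff_bound + (1 - b_t) * eff_free)` to the log
expression rate, where `b_t = [ligand]/([ligand] + K_lig)` is the bound
fraction and `occ_t = P_t/(P_t + K_op)` the promoter occupancy; the rate is
`basal * exp(sum w_t)`. This keeps rates positive, lets the sign of
regulation switch with the ligand state of the TF (as the model requires),
and reduces exactly to the basal rate for unregulated genes. Proteins decay
at the single global `degradation` rate, which applies to TFs, enzymes and
pumps alike.

## Fitness

Performance in one resource condition is measured at the dynamical steady
state: `deviation_A = |A_int - target_A|/target_A` (analogously X) and
`score = 1/(1 + deviation_A + deviation_X)`, a scale-free form that is 1
exactly on target and strictly decreasing in each deviation — "inversely
proportional to the deviation". Cells whose dynamics do not settle
(oscillate, diverge, or fail the convergence criterion within the time
horizon) score 0: failing to reach *any* steady state is a failure of
homeostasis by definition. A cell experiences one to three resource
conditions per lifetime, with `A_ext` drawn log-uniformly from 0.1–10 times
the standard concentration; its fitness is the geometric mean of the
scores. The geometric mean is non-decreasing in every score and punishes
failure in any single condition severely, which is what selects for
feedback regulation rather than a fixed compromise phenotype.

## Standard environment

The supplementary material specifying the original standard-environment
constants is not redistributed with this package, so the defaults of
`environment_params()` — `A_ext = 1`, `permeability = 1`,
`degradation = 0.5`, `conversion_rate = 1`, `target_A = target_X = 0.6`,
`K_op = 0.5` — are this package's own calibration, chosen once so that (i)
all quantities are order one, (ii) hitting both targets requires active
import at low resource and active disposal at high resource, and (iii) the
hand-designed fixture genome with two negative-feedback TFs scores well
above the viability floor. All analyses in the package compare simulations
to their own matched controls, so conclusions are about dynamics under a
common environment, not about particular constants.

# Mutation operators

Defaults in `mutation_rates()` follow the published regime: per cell and
generation, segmental duplication 0.024, segmental deletion 0.024,
translocation 0.048, WGD 0.003 (about a factor 10 below the summed
small-scale rates, hitting ~0.3% of a population per generation), and point
mutations hitting genes five times more often than large-scale events
(`point_per_gene = 5 * 0.096 / 50 = 0.0096`). The quoted segmental rates are
interpreted as probabilities at a reference genome size `G_ref = 50` that
scale linearly with the current gene count — this is the only reading that
reconciles fixed quoted rates with the (twice-stated) constancy of
*per-gene* rates across genome sizes; WGD stays size-independent. We read
"duplicated or deleted at 0.024" as 0.024 *each*, keeping the two operators
symmetric. Segment lengths are uniform on `1:ceiling(n/4)` ("up to a quarter
of the genome" fixes only the cap). At most one event of each kind is
attempted per cell per generation; at these rates multi-event corrections
are negligible and the one-attempt scheme keeps event logs trivially
replayable.

Point mutations pick one mutable attribute uniformly: positive kinetic
constants and basal rates take multiplicative log-normal steps (scale-free
for positive parameters), TF regulation strengths take additive Gaussian
steps (so signs can flip), motifs flip one random symbol, and TF ligands
toggle. The pump's energy stoichiometry (`cost`) is treated as part of the
reaction chemistry, not a mutable gene parameter. The step sizes
(`sigma_param = sigma_effect = 1.6`) are a deliberate calibration: they set
the deleterious load carried per gene. With much smaller steps a point hit
is nearly neutral, the load term almost vanishes, and selection for extra
gene copies (stronger fluxes, tighter homeostasis) drives unbounded genome
expansion — populations blow past several hundred genes with no
streamlining in sight, which is qualitatively the wrong regime: the model
this package implements streamlines invariably in the long run. At
`sigma = 1.6` a point hit is a substantial perturbation, genomes settle in
the tens of genes, and the expansion-then-streamlining pattern emerges.
The published per-gene mutation *rates* are untouched by this calibration.

Every operator returns, besides the mutated genome, a complete event record
(segment bounds, fresh gene ids, old and new parameter values).
`replay_events(parent, events)` reconstructs the child *exactly*, with no
randomness; this replay property is what makes line-of-descent analyses
exact rather than approximate, and it is asserted across thousands of random
mutation applications in the test suite.

# Population loop and experiment protocol

Populations have fixed size (1024 in the published protocol; the scaled
studies below use 100). Each generation every cell's fitness is evaluated
on its own lifetime draws, and offspring are sampled fitness-proportionally
with replacement; an all-zero-fitness generation (possible right after a
harsh environmental change) falls back to uniform sampling rather than
extinction. The high-fitness trigger of the two-stage protocol uses a
deterministic *standardized* fitness — the geometric mean over the fixed
`A_ext` multipliers (1/3, 1, 3) — evaluated for the generation's best cell;
a stochastic trigger would make the change point irreproducible. The
environmental change is applied exactly 1000 generations (default) after
the cutoff of 0.85 is first exceeded.

The perturbation panel changes exactly three of the five non-evolvable
parameters at a time, two levels each: `choose(5,3) * 2^3 = 80`
environments. Levels default to a factor 2 from standard, except the
degradation rate at factor 4 — inside the stated factor-2-to-4 bracket,
with the severest change on the parameter the original experiments single
out as most consequential.

# Lineage and retention analyses

## Ancestry bookkeeping

Ancestry is tracked by tags, not sequences (the model has no sequence-level
homology): copies created by any duplication inherit their template's tag
and a duplicate flag. Analyses that need per-lineage identity replay the
line of descent from a *retagged* reference: the genome at the reference
generation (environmental change, or the first post-WGD genome) gets fresh
unique tags, and the recorded events are replayed forward. Afterwards the
carriers of a tag are exactly the descendants of that reference gene, so

* ancestral content counts a tag once no matter how many copies exist
  ("only one random copy is the original"; the *count* is invariant to
  which copy is chosen, and `ancestral_representatives()` makes the random
  choice where identity matters, e.g. binding-site comparisons);
* duplicates arising after the reference never add content;
* an ohnolog pair is intact exactly when both members' lineages survive,
  and a conserved gene whose partner lineage died is a single — membership
  can only move from ohnolog to single, never back.

## Null models

`random_deletion_null()` replays the *observed* per-interval, per-category
loss counts of ancestral WGD genes on the reference genome without
selection. In uniform mode every surviving gene of the category is equally
likely to go; in connectivity mode TF deletion probabilities follow the
per-capita loss likelihood of the TF's ancestral-outdegree bin (quintiles
of relative outdegree by default), estimated per interval from the matched
evolutionary run — the calibration whose success is judged by reproducing
the run's retained-TF connectivity trajectory. Expected retention fractions
are averaged over 100 replicates by default, enough to stabilise the
curves; small cases are checked against exhaustive enumeration over all
deletion subsets in the tests.

Group differences (WGD vs non-WGD vs neutral lineages) use two-sided
Mann-Whitney rank-sum tests via `rank_sum_compare()`, one score per run:
per-run means over the whole interval for mutation rates, last-time-point
scores for retention, connectivity and divergence.

# Numerical choices

The integrator is a stabilized explicit Runge-Kutta-Chebyshev (RKC2)
scheme with adaptive step size, embedded second-order error estimate and a
power-iteration estimate of the Jacobian spectral radius. These reaction
systems are dissipative and mildly stiff (protein decay is slow, metabolite
turnover fast); RKC handles that regime at a fraction of the cost of a
classical explicit method, and a Cash-Karp RK45 integrator is retained as
an independent cross-check (`ss_control(method = "rk45")`); the test suite
verifies that both, and an external stiff solver, agree on steady states.
Convergence is declared when `max |dy_i/dt| / (1 + |y_i|) < conv_tol`
(default `1e-6`) before the time cap `t_max` (default 1000 time units);
non-converged or non-finite dynamics score 0. States are clamped at zero
(concentrations cannot go negative; the clamp only ever absorbs
integration undershoot). Steady states are insensitive to the tolerance
and method choice because every run terminates on the same
derivative-based criterion.

Evaluations inside the evolutionary loop use relaxed settings
(`t_max = 80`, `rtol = 2e-3`, `conv_tol = 1e-4`, and a budget of 1500
right-hand-side evaluations per solve): only the attractor matters for
scoring, the convergence test is applied to the true derivative either
way, and a cell that cannot settle within 80 time units — or whose
dynamics are so extreme that the evaluation budget runs out, or whose
Jacobian spectral radius exceeds `1e8` (runaway regulation) — is failing
homeostasis on the timescale that matters and scores 0. A Newton
refinement of the fixed point is attempted once the trajectory has nearly
settled; its result is accepted only when it stays local to the state the
trajectory was approaching, so limit cycles and drifting states still
count as non-converged. The analysis API keeps the strict defaults
(`t_max = 1000`, `rtol = 1e-6`, `conv_tol = 1e-6`).

Ties and degenerate inputs: empty genomes are inviable (fitness 0); a WGD
on an empty genome is a warned no-op; an all-identical rank-sum input
returns p = 1 with a warning; retention fractions with empty denominators
are reported as `NA` rather than imputed.

# The synthetic-data generators

`make_viable_genome()` builds the minimal regulated metabolism — pump,
catabolic enzyme, anabolic sink, an A-sensing TF repressing the pump and an
X-sensing TF repressing catabolism — with kinetic presets frozen so its
standard-environment score (about 0.69) clears the fixture contract floor
of 0.5. `make_synthetic_lod()` applies a deterministic scripted event list
to a reference genome, giving analyses closed-form expected values
(censuses, conservation curves, rate bins) without running evolution. These
generators emulate the *bookkeeping* of real runs exactly — the events are
the same replayable objects the simulator produces — but not their
statistics: passing fixture-based tests shows the analysis machinery is
correct, not that evolution produces any particular retention pattern. The
latter is what the scaled replication study measures.

# The scaled replication study

`run_scaled_study()` reruns the full two-stage protocol at desk scale:
populations of 64 cells with founding genomes of 12–24 genes, an initial
adaptation stage of 150 generations, and three 100–250-generation branches
per replicate (neutral continuation, re-adaptation with WGD imposed at the
change point, re-adaptation under natural mutation pressure only), with
census bins of 50 generations — about 700 simulated generations per
replicate over ten replicates, against the published 15000-generation,
1024-cell experiments. Probes at substantially longer horizons (500-700
generation branches) left every qualitative outcome below unchanged while
quadrupling the cost, so the short horizons are not hiding a
longer-timescale reversal within reach of desk hardware. These sizes are the package's own choice of what a
desk-scale replication should cost; every stage length, the population
size and the replicate count are arguments of `run_scaled_study()` and can
be raised towards the published protocol on bigger hardware. Two protocol adaptations are deliberate:

* **Conditioning on WGD.** At full scale, lineages that fixed a WGD are
  found by running 800 re-adaptation simulations and selecting; at desk
  scale spontaneous fixation is too rare to guarantee any WGD lineages
  among ten replicates. The retention branch therefore applies a WGD to
  the whole population at the change point (logged as ordinary, replayable
  WGD events) — i.e. we condition on the event whose aftermath the
  retention analyses measure. The published observation that accepted WGDs
  cluster within 500 generations of the change is what makes this
  conditioning faithful. The *natural* branch, used for the
  WGD-fixation-frequency direction, is never forced.
* **Shorter horizons.** With 100-generation bins the analyses resolve the
  same qualitative features (initial divergence burst, streamlining
  decline, retention bias) on the shorter timescale. Quantities that need
  15000 generations to equilibrate (final retention plateaus, the full
  two-thirds neutral content loss) are checked at trend/direction level
  only.

What the scaled study *does* show: rising fitness under the protocol,
genome streamlining after an expansion phase, and spontaneous WGD fixing
in a minority of re-adapting lineages. Three full-scale findings do
**not** reproduce reliably at this scale, and the package reports them
honestly rather than relaxing the checks:

* *Over-retention of TF ohnologs against the uniform null.* The
  intact-pair statistic separates evolved runs from the null only after
  deep attrition of WGD-derived content, which takes thousands of
  generations; worse, at shallow attrition the statistic is biased the
  other way, because segmental deletions remove adjacent genes while the
  two members of a pair sit maximally far apart on the circular genome, so
  evolved losses collide within a pair *less* often than independent
  uniform deletions do. Promoter-occupancy saturation additionally damps
  the dosage sensitivity of TFs at small population sizes. Expect this
  comparison to come out flat (or slightly inverted) at desk scale.
* *Connectivity bias of retained TF ohnologs.* The relative ancestral
  outdegree of retained ohnologs hovers around 1 (observed means between
  0.94 and 1.31 across horizons and seeds) instead of sitting clearly
  above it: with only a handful of TF pairs per replicate and shallow
  attrition, the retained set is usually most of the ancestral set, which
  forces the ratio towards 1 and leaves it drift-dominated.
* *Majority loss of ancestral gene content under neutral continuation.*
  A few hundred neutral generations lose on the order of 15–35% of the
  ancestral content; the published two-thirds accrues over 15000
  generations.

What the study also does not address: the published magnitudes at full
scale, biased fractionation, or anything about hybrid polyploidy (the
model duplicates genomes strictly clonally).
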