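---
title: "Inferring clonal architecture from single-cell Q-PCR genotypes"
author: "CloneArch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clonal architecture from single-cell Q-PCR genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CloneArch)
```

## The problem

In NPM1c-mutant acute myeloid leukaemia (AML), a handful of driver
mutations identified by targeted sequencing of the bulk sample
(DNMT3A, TET2, NPM1c, FLT3-ITD, WT1, IDH2, ...) are distributed across
genetically distinct sub-clones. Bulk allele frequencies only weakly
constrain that sub-clonal structure. Multiplex Q-PCR on single sorted
cells resolves it directly: each well of a 48x48 microfluidic array holds
one cell from a sorted compartment — bulk blasts (CD33+/CD34-/CD3-), the
small putative stem-cell fraction (CD34+/CD33-), T cells (CD3+, a
germline control), or unsorted cells regenerated in an immunodeficient
mouse — and is assayed for every tracked mutation plus a diploid control
locus (B2M).

CloneArch implements the full analysis chain over such data:

1. **Genotype calling** (`callGenotypes`): per-well channel signals to
   ternary WT/MUT/MISSING calls with control-locus QC.
2. **Clone calling** (`callClones`): per-cell genotypes to sub-clones
   with per-compartment counts, dropout-aware merging, and a
   detection-limit model (`detectionProbability`).
3. **Phylogeny** (`searchMPTrees`): maximum parsimony over the observed
   clone genotypes rooted at germline, enumerating *all* equally
   parsimonious trees, with an independent brute-force oracle
   (`mpBruteForce`).
4. **Interpretation** (`mutationPrecedence`, `detectReiterated`,
   `mapCloneSets`, `cohortSummary`): mutation order and truncal status,
   parallel (reiterated) gains, and mapping of xenograft/relapse clone
   sets onto the diagnostic clones.
5. **Simulation** (`simulateCloneTree`, `simulatePopulation`,
   `sampleChip`, `simulateXenograft`): seeded synthetic chips with the
   statistical structure the analysis assumes, so every stage is
   testable by parameter recovery without any external data.

## Genotype calling

Two assay chemistries are modelled. *Allelic discrimination* assays
carry a VIC-labelled wild-type probe and a FAM-labelled mutant probe:
the WT channel amplifies whenever a wild-type allele is present, the MUT
channel whenever a mutant allele amplifies. *Mutant-only* assays are
used for indels and FLT3-ITDs, where no wild-type probe can span the
breakpoint.

The calling rule per cell, with amplification defined as a Ct below the
configurable threshold (default 30):

* control channel not amplified → the cell is `control_fail` and drops
  out of every downstream denominator (no imputation);
* allelic discrimination: MUT amplified → `MUT` (dual amplification is a
  heterozygous cell, so the WT channel state is not consulted further);
  WT only → `WT`; neither → `MISSING`;
* mutant-only: MUT amplified → `MUT`; otherwise `WT` when the cell's
  control locus amplified (the well demonstrably contained amplifiable
  DNA) and `MISSING` when it did not.

Zygosity is deliberately collapsed: `MUT` means "mutant allele
detected". Mutant-only assays cannot distinguish het from hom, and
clone genotypes downstream are presence/absence vectors. The exact
thresholds and replicate handling of any particular instrument are
configuration, not constants.

This rule set is idempotent: re-calling a chip reconstructed from a
called matrix (`genotypesToChip`) returns the identical matrix, which
the test suite asserts on noisy simulations.

## Clone calling and the detection limit

QC-passing cells are collapsed into genotype profiles. Complete profiles
observed in at least `minCells` cells (default 2, summed over
compartments) become clones. Two sources of error are handled
explicitly:

* **Allele dropout (ADO).** A heterozygous locus whose mutant allele
  fails to amplify reads falsely wild type, so dropout artefacts are
  strict *subsets* of a real clone's genotype. A sub-threshold profile
  that is a strict subset of exactly one called clone within
  `maxAdoLoci` loci (default 1) is merged into that clone; ambiguous
  sub-threshold profiles stay unassigned.
* **Missing calls.** An incomplete profile is assigned iff exactly one
  called genotype (including the germline reference) agrees with all its
  non-missing calls; otherwise the cell is retained in denominators but
  not in any numerator.

All-wild-type cells are germline reference (normal contaminating
cells), never a clone. Per compartment, assigned + germline + unassigned
cells equal the informative pass cells as an exact integer identity.

Clones whose frequency is below `minFreq` (default 0.05) in every
compartment are flagged `low_frequency`, never deleted: with n cells
assayed, a clone at frequency f is sampled at least once with
probability 1-(1-f)^n — about 0.915 for f = 0.05 at n = 48 — so minor
clones sit at the edge of detectability, and clonal complexity is more
likely under- than over-estimated. Frequencies are reported with Wilson
95% intervals, which always contain the point estimate.

## Maximum parsimony over observed clones

The search space is the set of rooted spanning arborescences over
{germline} ∪ observed clones. Observed clones may be internal
(ancestral) nodes; hypothetical unobserved (Steiner) intermediates are
out of scope, because only observed genotypes carry evidence here. The
default *irreversible* model permits only gains along an edge (somatic
point mutations do not revert); an edge costs the number of mutations
gained, and an edge losing a mutation is an error. *Free* mode scores
the full symmetric difference and is retained for sensitivity analysis.

Because equally parsimonious trees are common at this scale and are
themselves a finding (alternative clonal histories), the search returns
the **complete co-optimal set**, canonically ordered: up to
`exhaustiveLimit` nodes (default 7, i.e. 7^5 parent vectors) every
arborescence is enumerated; above it, a branch-and-bound over partial
parent assignments (clones placed in ascending mutation count, ties by
id) prunes a branch only when accumulated cost plus a per-clone
cheapest-incoming-edge bound strictly exceeds the best known score, so
completeness is preserved. `consensusEdges` intersects the co-optimal
set: shared edges are the resolved backbone, the rest are alternative
histories.

Correctness is established against an independent oracle,
`mpBruteForce`, which enumerates all parent vectors (n^(n-2) rooted
arborescences for n nodes after the acyclicity filter), scores each from
the definitions, and returns the co-optimal set. The test suite checks
score *and* tree-set identity on hundreds of seeded random clone sets in
both modes, plus two analytic facts: the minimum score is bounded below
by the number of distinct observed mutations, with equality exactly when
no mutation must be gained twice; and the irreversible minimum is never
below the free-mode minimum.

## Interpretation

**Mutation order** is derived from genotype containment, not from any
single tree: a precedes b iff every called clone carrying b also carries
a and some clone carries a without b. Under the irreversible model this
is sound and robust to which co-optimal tree is real, which is why
containment, rather than a tree traversal, is the primary engine. A
mutation present in every called clone is *truncal* (the DNMT3A/TET2
founder pattern); the rest are sub-clonal (the NPM1c pattern). A pair
that cannot be ordered is `parallel` when one of its mutations is gained
on more than one edge in every co-optimal tree, `unresolved` otherwise.

**Reiterated mutations** (homoplasy — e.g. two independent TET2 lesions
in separate sub-clones) are reported per co-optimal tree, with the
intersection across trees reported separately; the package does not
adjudicate mutations reiterated in only some co-optimal trees.

**Xenograft/relapse mapping** classifies each query clone against the
diagnostic reference by set relations on the shared panel, in strict
precedence order: `matched` (genotype equality), `novel_descendant`
(strict superset — extra mutations acquired, or a clone that was below
the detection limit at diagnosis), `ancestral` (strict subset — a
pre-leukaemic read-out), else `unrelated` (defensive completeness; real
cohorts rarely need it). Clone identity across samples is exact genotype
equality — dropout-mediated near-matches must be resolved upstream, not
fuzzily here. The dominant graft clone is the most frequent, ties broken
by id.

## The synthetic-data generator

`simulateCloneTree` grows a random irreversible tree in which every
clone gains at least one fresh mutation, making genotypes automatically
distinct. With `founderFirst`, a designated founder mutation
(DNMT3A-like) is gained on the single edge out of germline and all other
clones descend from that clone, making the founder truncal by
construction; a designated secondary mutation (NPM1c-like) is gained
strictly later, so at least one clone carries the founder without it.
With a single clone the order is not expressible — as in a real
one-clone patient — and the secondary mutation stays unused; recovery
tests therefore evaluate the order property over runs with at least two
clones and truncality over all runs. With `allowReiteration`, one
mutation is additionally gained on a second branch, and the placement is
accepted only when the resulting carrier clones have no common contained
carrier — a condition that forces at least two gains in *every*
irreversible tree, so planted homoplasy is genuinely detectable rather
than an accident of the generating topology.

`simulatePopulation` emulates the three diagnostic compartments: blasts
(leukaemic clones only), the stem fraction (10% germline admixture by
default, weights biased towards mutation-poor ancestral clones,
emulating compartment-restricted pre-leukaemic clones), and the T-cell
control (germline at frequency 1). Each clone receives a frequency floor
(default 0.15 of the blast compartment, capped at 0.9/k for k clones).
The floor is a deliberate design choice: at 48 cells per compartment it
puts every simulated clone's expected cell count near 7 per compartment
(~13 across the two diagnostic compartments), far above the 2-cell
calling threshold, so parameter-recovery tests probe the method rather
than multinomial sampling noise. Sampling sensitivity itself is modelled
and tested separately through `detectionProbability`.

`sampleChip` draws a clone per well from the compartment's frequency
vector and emits Ct signals. Amplified channels draw a Ct from a normal
distribution clamped strictly below the threshold (rounded to 3
decimals so chip CSVs round-trip exactly); "no amplification" is an
absent value. The noise model is per (cell, locus) independent: mutant
dropout `ado` (false WT), false positives `fp`, whole-assay failure
`locus_fail`, and control failure `cell_fail` (defaults 0.1 / 0 / 0.05
/ 0.05; the source study does not report its empirical rates, so these
are exposed configuration, not constants). Only mutant-allele dropout
changes a call, because a heterozygous cell's wild-type allele keeps the
WT channel amplifying regardless.

`simulateXenograft` is purely a frequency-vector transformation: a
dominant regenerating clone at frequency ≥ `dominance`, the residual
mass spread over a permitted subset of clones — possibly clones at
frequency 0 in every diagnostic compartment, emulating a graft clone
below the detection limit at diagnosis.

What the generator does *not* emulate: doublets and sorting impurities,
PCR efficiency gradients across a chip, segmental losses or copy-number
events (which can mimic reversion), and correlated dropout between loci.
Passing recovery tests therefore demonstrate correctness of the
analysis logic under the stated noise model, not robustness to every
artefact of real chips.

## Problem sizes, numerical choices and determinism

* Verification runs use clone sets of 2–6 clones over 3–8 mutations
  (200 seeded cases, both modes) for oracle equivalence; 100 noise-free
  founder-first cohorts of 1–6 clones at 48 cells per compartment for
  truth recovery; a 4-level dropout sweep (ado 0, 0.05, 0.1, 0.2; 50
  seeds each; 2–4 clones) for robustness; and 50 seeded xenograft
  scenarios read out at 96 cells. These sizes match the study design
  (up to 6 clones per patient, 48/96-well chips) while keeping the
  whole suite fast.
* Recovery collapses quickly with dropout (at ado 0.05 most runs
  acquire at least one spurious subset-clone seen in ≥2 cells), and the
  co-optimal set inflates correspondingly; the tested contract is the
  monotone trend, not a particular rate.
* Every stochastic operation takes one integer seed and uses an
  isolated RNG scope (`withr::with_seed`), so identical seeds give
  bit-identical outputs and the global RNG state is never disturbed.
* All writers are deterministic (no timestamps; fixed column and row
  order; canonical tree ordering by edge-list serialisation), so
  equal-config pipeline runs are byte-identical. The run log records the
  package version and a hash of the analysis-relevant configuration
  (the output directory is excluded, so runs into different directories
  still compare equal).
* Ties are broken lexicographically everywhere (clone ids by descending
  count then genotype string; dominant clones by id; B&B expansion by
  node order), which makes every reported structure reproducible.

## Limitations

* Precedence from containment cannot order mutations that never
  co-occur in a called clone; such pairs stay `unresolved` rather than
  being forced into an order by a single arbitrary co-optimal tree.
* The irreversible model treats a genotype lacking a mutation as never
  having had it; deletions spanning an assayed locus would violate this
  silently.
* Clone identity across samples is exact genotype equality on the
  shared panel; panels must be harmonised upstream.
* The brute-force oracle is limited to 8 nodes by design; beyond that,
  completeness rests on the branch-and-bound argument, which the suite
  cross-checks against the oracle in the regime where both run.
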