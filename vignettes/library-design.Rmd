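---
title: "Designing novelty-optimized screening libraries with screenlib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing novelty-optimized screening libraries with screenlib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A general-purpose screening library should contain drug-like, chemically
diverse compounds that are likely to be bioactive, with a bias towards
protein targets of current research interest. `screenlib` implements a
complete pipeline for composing such libraries from an arbitrary pool of
purchasable compounds:

1. **Curation** — structure standardization, eligibility checks and a
   drug-likeness filter cascade reduce the raw pool to well-behaved
   candidates.
2. **Target prediction** — each candidate inherits the known targets of
   sufficiently similar reference compounds (2D Morgan/Tanimoto
   similarity against a curated bioactivity table).
3. **Novelty annotation** — targets are grouped into Pfam families, and
   each family receives a novelty score derived from the publication
   dates of its bioactivity records.
4. **Subset selection** — an elitist genetic algorithm (GA) picks the
   N-compound subset maximizing a novelty-weighted, diversity-rewarding
   fitness function.

This vignette documents the model, its tunable parameters, the numerical
choices made where the design was genuinely open, and what the synthetic
data generators do and do not emulate.

## Curation model

Input SMILES are standardized before any property is computed: the
largest organic fragment is kept (salts and solvents are stripped),
formal charges are neutralized where chemically possible, the canonical
tautomer is selected, and stereochemistry is removed so compound identity
is purely constitutional (stereo annotation of purchasable compounds is
often unreliable). Duplicates arising from standardization are merged,
keeping the lexicographically smallest identifier so the result is
independent of input order. Standardization is idempotent, which the test
suite asserts rather than pinning exact output strings (canonical SMILES
and tautomer choices are toolkit-version dependent). The chemistry
primitives themselves — parsing, canonicalization, descriptors,
fingerprints, scaffolds — are delegated to RDKit through a bundled batch
helper (`inst/python/chemtool.py`); every algorithmic step above that
layer is implemented in R.

Eligibility requires a molecular weight of 250–900 Da and an elemental
composition limited to C, H, O, N, P, S, F, Cl, Br and I. The property
cascade then removes compounds with any of: fewer than 18 or more than 30
heavy atoms; fewer than 1 or more than 4 rings (smallest set of smallest
rings); a ring system with more than 3 fused rings; more than 8 rotatable
bonds; more than 3 hydrogen-bond donors; more than 7 acceptors; a
formally charged carbon atom; no nitrogen or oxygen; a match to a
structural-alert SMARTS; or a tosyl group (`S(=O)(=O)O`). Verdicts list
*every* violated rule rather than stopping at the first, which makes
rejection reports auditable. Two open points were settled as follows:

* **Fused-ring definition.** Rings sharing at least one atom are merged
  into one system, so spiro junctions count as fusion. This is the
  conservative superset of "fused" and matches an atom-overlap reading of
  SSSR ring membership.
* **Structural alerts.** Published alert collections are licensed
  collections of hundreds of SMARTS; they are consumed as a user-supplied
  table (`name`, `smarts`). Only the tosyl pattern ships built-in, and
  `example_exclusion_patterns()` provides a minimal nitro alert for
  demonstrations and tests.
* **logP** is computed and reported but never filtered on: upstream
  vendor catalogs are assumed to have applied their own logP window, and
  re-filtering after standardization would silently shift the pool.

## Target prediction

Reference bioactivities are curated with fixed record-level criteria
(assay confidence 6–9, no potential duplicates, validity comment absent
or "manually validated", measurement type in {Kd, Potency, AC50, IC50,
Ki, EC50}, no inconclusive/unspecified comments, and a stated relation
unless the record is explicitly "Active"). Values reported in µg/mL are
converted to nM via `value * 1e6 / mw`. Duplicate (compound, target)
pairs are merged to their median activity (mean of the two middle values
for even counts), and pairs at or below 10,000 nM are labeled *active*.
Merging precedes thresholding; the merged record keeps the earliest
non-missing publication year, the most conservative choice for novelty
dating since it reflects first disclosure.

Each query compound is fingerprinted (Morgan, radius 2, 2048 bits) and
compared against every reference entry. All entries with Tanimoto
similarity ≥ 0.5 contribute their active targets, and the prediction is
the union — not only the single nearest neighbor — because the retention
rule is the threshold, and any neighbor above it carries evidence.
Compounds whose best similarity falls below 0.5 are *dark chemical
matter*: nothing can be predicted for them, so they are excluded from the
pool of candidate compounds (PCC) that the GA samples, but they remain in
the filtered pool from which baseline libraries draw.

## Novelty and fitness

Targets are mapped to Pfam families (the mapping table is an input;
producing it from HMM scans is upstream of this package). Targets without
a family share a single dummy family: their mutual similarity is unknown,
so treating them as one family is the conservative choice. For each
family,

$$\mathrm{novelty} = \frac{n_{\ge 2010}}{n_{\ge 2010} + n_{< 2010}}$$

over its dated bioactivity records, a record contributing to every family
of its target. A record dated exactly 2010 counts in the numerator.
Families with no dated records receive the mean score of the directly
scored families as a fallback. Per-target novelty (used for report
medians) is the mean over the target's families; the spread between a
target's families is typically small, and the mean is the least
surprising combination rule.

The fitness of an N-compound library is

$$\mathrm{fitness} = \frac{1}{N} \sum_{\mathrm{family}\ f}
  \mathrm{novelty}_f \cdot \frac{1 - r^{c_f}}{1 - r}, \qquad r = 0.99,$$

where $c_f$ counts the *distinct* library compounds predicted to interact
with at least one target of family $f$. Each repeat hit on a family adds
$\mathrm{novelty}_f \cdot r^{c}$ — positive, but strictly smaller than
the previous increment — so the function rewards both breadth (new
families) and credible depth (repeat hits), with diminishing returns. At
$r = 0.99$ the per-family sum plateaus slowly, keeping depth valuable up
to hundreds of repeats; `r` is configurable for sensitivity analysis. An
alternative reading counts predictions rather than distinct compounds
(a target hit twice in the same family counting twice); it is available
via `count_mode = "predictions"` but is not the default, since the
distinct-compound count is what makes repeat evidence *independent*.
Fitness scores are comparable only between libraries of equal N — the
normalization removes additive, not saturating, size effects — so every
report carries N alongside the score.

## The genetic algorithm

An *individual* is an ordered sequence of N distinct compound ids from
the PCC; a *population* holds M individuals. Each generation:

1. The P fittest individuals are carried over unchanged (elitism), with
   ties broken by earlier index. P is the largest even number ≤ M/3 and
   at least 2 — "a third of the population" needs a rounding rule, and an
   even P pairs without remainder. M < 6 is rejected.
2. Parents are paired uniformly at random without replacement. Each pair
   produces four children from a midpoint split (halves $A_1A_2$ /
   $B_1B_2$ give $A_1{+}B_2$, $B_1{+}A_2$, $A_1{+}B_1$, $A_2{+}B_2$; for
   odd N the B-halves are sliced to complementary lengths so every child
   has exactly N slots). Pairings are redrawn until the M − P child
   slots are filled; surplus children are discarded in generation order.
3. Children are *repaired* — every later duplicate occurrence is replaced
   by a uniform draw from the pool compounds not already in the child —
   and then *mutated*: ⌊0.10 · N⌋ random positions are replaced with pool
   compounds not present in the child. Repair precedes mutation so the
   mutation always acts on a valid individual. Mutation draws come from
   the PCC only.
4. Parents and children form the next population of size M.

After 300 generations (default) the fittest individual is the selected
library. Elitism makes the per-generation best fitness non-decreasing,
which the test suite asserts on every run it performs. A single seeded
RNG stream governs initialization, pairing, repair and mutation, so a
(configuration, seed) pair reproduces a run bit-for-bit; the run manifest
records both.

Baseline libraries — the comparison point for optimization gains — are
the fittest of max(1, ⌊0.1 · N⌋) uniformly random N-subsets of the
*filtered* pool, dark matter included, with no evolution.

## Characterization

Libraries and pools are described by: number of unique Murcko scaffolds
(acyclic molecules share the empty scaffold), Taylor-Butina clusters at
Tanimoto ≥ 0.4 (similarity, not distance), unique predicted targets,
Pfam families, predicted bioactivities (the sum of per-compound target
counts), median target novelty over unique targets, and QED/logP
summaries. The Taylor-Butina implementation follows the classic leader
algorithm: the unassigned compound with the most unassigned neighbors
becomes the next centroid (ties to input order), claims its unassigned
neighbors, and compounds whose neighbors were all claimed earlier become
false singletons.

## Synthetic data generators

Real inputs at publication scale (millions of compounds, a full
bioactivity database) are not needed to validate the machinery, and the
package ships two deterministic generators instead.

The **annotation-tier generator** (`synth_annotation_pool()`) emulates
the statistical shape of a curated pool downstream of chemistry, with
defaults chosen to mirror a realistic instance: 10,000 compounds of which
49% are dark matter (the fraction a threshold of 0.5 leaves without
predictions in a large purchasable pool); per-compound target counts from
a zero-truncated negative binomial with mean ≈ 3 (matching the predicted
bioactivities-per-compound of optimized libraries); 300 targets and 120
families with power-law popularity, 10% of mapped targets carrying two
families and 2% unmapped (dummy); per-family novelty propensities drawn
from Beta(3.5, 1.5), centering realized novelty scores near 0.7 with a
recent-side skew; record years spanning 1995–2020 with 4% undated. The
emitted record table is the only source of the novelty table — the
generator never writes scores directly — so realized scores always equal
their recomputation from records.

The **chemistry-tier generator** (`synth_chemistry_pool()`) enumerates
substituted two-ring amide/sulfonamide structures from a fixed template
grammar verified to satisfy every filter bound under all substituent
combinations, plus salt/charged input forms that standardize onto the
grammar, plus the single-rule violator panel of `filter_rule_fixture()` —
one hand-designed structure per filter rule, each violating exactly that
rule. What these generators deliberately do **not** emulate: real
structure–activity correlation (fingerprint similarity is unrelated to
the synthetic predictions), assay noise, vendor catalog redundancy, and
family-size/target-promiscuity correlations. Passing tests therefore
demonstrate that the machinery is correct and effective on pools with
realistic marginal statistics, not that any particular real pool would
yield a specific fitness value.

## Problem sizes and numerical choices

The test suite and the acceptance script run at scales chosen to finish
comfortably on a laptop while still being informative: fitness is checked
against a term-by-term summation oracle on 1,000 random libraries (rel.
error < 1e-9); GA optimum recovery is checked on a 12-compound pool with
4-compound libraries, where all 495 subsets can be enumerated; the
optimization-effect benchmark evolves a 500-compound library from the
10,000-compound synthetic pool (M = 50, 150 generations, ~5 s) against a
50-draw baseline, and typically roughly doubles the baseline fitness —
the same direction, and a comparable magnitude, as the gains the method
yields at full scale. Degenerate inputs are handled explicitly: empty
libraries score 0; a pool exactly of size N forces identical individuals;
all-zero fingerprints have similarity 0 to everything; an empty reference
set is an error rather than an empty prediction.

## Known limitations

* Standardization fidelity is bounded by the toolkit: tautomer
  canonicalization occasionally disagrees between toolkit versions, which
  can split or merge borderline duplicates.
* The similarity search is a dense matrix computation, appropriate up to
  ~10^5 × 10^5 fingerprint comparisons per chunk; production-scale pools
  (10^6+) would want a bit-packed or indexed search arena behind the same
  `predict_targets()` surface.
* Novelty depends on publication-year metadata; families dominated by
  undated records inherit the fallback mean, flattening their signal.
* The GA is a single-population elitist design; it finds near-optimal
  subsets reliably at the scales tested but makes no global-optimality
  guarantee for large N.
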