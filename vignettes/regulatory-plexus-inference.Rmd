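---
title: "Inferring a promoter's regulatory plexus from accessibility correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a promoter's regulatory plexus from accessibility correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regplexus)
```

## The problem and the model

A gene's *regulatory plexus* is the set of cis-regulatory elements (CREs)
— enhancers, promoters, interaction anchors — that act on its promoter.
Chromatin contacts are constrained by topologically associating domains
(TADs), so candidate CREs for a gene are the accessible regions (DNase I
hypersensitive sites, DHS) inside the gene's TAD. Among those candidates,
the ones whose chromatin accessibility rises and falls *with the
promoter's accessibility across many cell types* are the ones most likely
to be functionally coupled to it.

`regplexus` operationalizes this in three steps:

1. **Window selection.** Candidates are the DHS overlapping the TAD
   padded by `padding_bp` on each side (default 40,000 bp, one Hi-C bin:
   TAD boundary calls are only accurate to the map resolution, so the
   window absorbs that uncertainty). Coordinates are BED convention
   throughout — 0-based, half-open `[start, end)` — so a DHS starting
   exactly at the padded window end is *not* a candidate.
2. **Anchored correlation.** For a region × cell-type accessibility
   matrix, each candidate's profile is correlated (Pearson) with the
   anchor's profile. The aggregation from per-base coverage to a matrix
   cell is the mean per-base signal over the region, with uncovered bases
   contributing zero; a sum statistic is available via `stat = "sum"`.
   No transform is applied to the aggregated values by default.
3. **Thresholding.** Plexus members are candidates with *defined* r
   strictly greater than `threshold` (default 0.7, the conventional
   cutoff for accessibility-correlation CRE linkage). The strict
   inequality is an observable boundary choice: a candidate at exactly
   r = 0.7 is excluded. Candidates whose correlation is undefined —
   constant profile, or fewer than 3 unmasked cell types shared with the
   anchor — are reported with a reason code (`zero_variance`,
   `too_few_pairs`) and counted separately, never imputed and never
   members. The anchor is never a member of its own plexus.

Downstream, the **annotation cascade** intersects members with chromatin
tracks. Only the designated *activity track* (an H3K27ac peak set from
tumors, marking active regulatory chromatin) filters; transcription-factor
tracks annotate but never filter. Somatic SNVs (1-based VCF positions,
converted at assignment time) are assigned to the *active* members —
variants in unmarked members are deliberately not counted, matching the
filter ordering of marking first, mutation second. A variant falling in
several overlapping regions is assigned to all of them. The cascade report
carries the stage counts (window DHS ≥ plexus members ≥ active ≥ mutated),
the variant and distinct-tumor tallies, and the mutated fraction printed
as a percentage rounded half-up to one decimal.

## The permutation essentiality test

Given per-cell-line essentiality scores (normalized Z scores from
knockdown screens; lower = more essential), the question is whether a
designated group of lines is unusually essential for the gene. The
statistic is the group median; the null is built by drawing groups of the
same size uniformly without replacement from the full panel — including
the target group, since the draw convention is "randomly selected cell
lines" from all lines; an `exclude_group` flag flips this. The one-sided
lower-tail p counts background medians ≤ observed.

Two conventions matter:

* **Resolution floor.** In Monte-Carlo mode `p = max(b, 1) / n_perm`:
  a zero exceedance count is reported as `1/n_perm` (flagged `at_floor`),
  because a permutation test cannot certify a p-value below its own
  resolution. At the default one million draws the floor is `1e-6`.
* **Exhaustive mode.** When `choose(n, k)` ≤ 1e6 all subsets are
  enumerated and `p = b / choose(n, k)` exactly; larger enumerations are
  refused with a pointer to Monte-Carlo mode.

Draws are generated from a single seeded RNG per call by vectorized
rejection: oversample k-tuples with replacement, redraw the rows that
contain duplicates. This keeps one million median-of-8 draws under ~5 s
in pure R and is reproducible for a fixed seed and algorithm version.

Percentile ranks (used for expression/essentiality placement) follow the
inclusive convention `100 · #(reference ≤ value) / n`.

## Experiment-scoring statistics

The `diffstats` functions reproduce the computations used to score
perturbation and allele-specific experiments on tabulated replicate
measurements:

* `relative_expression()`: target/housekeeping ratio per replicate,
  normalized to the mean basal ratio; percent change is
  `100(1 − mean treated normalized)`. Invariant to global rescaling.
* `student_t_two_sample()`: pooled-variance two-sample t, two-sided
  (`df = n_a + n_b − 2`). "Student's t" is read as the equal-variance
  test — that is what the name denotes — and two-sided as the
  conservative default, since sidedness is rarely stated.
* `mann_whitney_u()`: exact enumeration p when the combined sample is
  ≤ 12 with no ties, else the tie-corrected normal approximation. The
  switch point is documented because reporter-assay p-values near 0.05
  are decision-relevant.
* `allele_log2fc()`: per-replicate `log2(variant/wildtype)` with pairing
  by replicate id when ids match across alleles, and a mean-wildtype
  denominator fallback otherwise (whether ChIP replicates are paired
  across alleles is usually not knowable from the table, so both routes
  exist and the result records which was used). Significance is the
  pooled t test on log2 enrichments.
* `efficiency_expression_correlation()`: Pearson r with the two-sided
  p from `t = r·sqrt((n−2)/(1−r²))`.

No multiple-testing correction is applied by default (single-element
tests are reported unadjusted); `adjust_bh()` is available when many
elements are tested at once.

## What the synthetic generator emulates

`simulate_accessibility_panel()` plants ground truth with the structure
the analysis assumes: a latent anchor profile i.i.d. standard normal over
cell types; member profiles `rho·anchor + sqrt(1−rho²)·noise`; background
independent. A single global affine shift makes all values non-negative —
Pearson correlation is location/scale invariant, so the planted
correlation structure is untouched. Regions are 500-bp intervals laid out
with ≥ 120 bp gaps inside a synthetic 440-kb TAD, with background both
inside the TAD, in the 40-kb padding zones, and beyond the padded window,
so window selection has real work to do. The defaults (ρ = 0.95, 50 cell
types, 200 background regions) make recovery essentially deterministic:
the sampling s.d. of r at ρ = 0.95 with 50 cell types is ≈ 0.014, so
planted members exceed the 0.7 threshold and independent background stays
far below it with overwhelming probability — which is precisely what
makes the truth manifest a usable oracle for the cascade.

`simulate_tracks_and_variants()` marks a chosen fraction of members with
activity peaks jittered 10–50 bp past the region edges (less than half
the guaranteed inter-region gap, so a peak never touches a neighbour),
plants SNVs uniformly inside a subset of marked members, and assigns
tumor ids so that every pool tumor contributes at least one variant when
counts allow — making the distinct-tumor tally deterministic. The default
study fixture plants 12 members, marks 8, mutates 3 with 5 SNVs from 4
tumors. `simulate_essentiality()` draws standard-normal scores and shifts
the group by `−effect_delta`; `force_extreme` instead places the group
strictly below the background minimum, the configuration in which the
permutation test must sit exactly at its floor.

What the generator does **not** emulate: read-level noise, peak-calling
artefacts, cross-cell-type normalization differences, correlated
background (e.g. co-regulated neighbouring DHS), chromatin-state
structure, or matched Hi-C contact maps. Passing the planted-recovery
tests therefore demonstrates that the inference machinery is correct,
not that a 0.7 correlation threshold has any particular sensitivity or
specificity on real accessibility panels, where background correlations
are far from independent.

## Numerical and design choices

* Coordinates: BED 0-based half-open for intervals; variants 1-based
  (VCF convention), converted once at assignment time.
* Chromosome dialects ("chr14" vs "14"): exact string match by default;
  a complete cross-dialect mismatch warns and suggests
  `normalize_chrom = TRUE`, which strips the prefix on both sides.
  Silent mis-joins are worse than a loud zero.
* Strand is carried on intervals but ignored by all overlap logic.
* Overlap joins run on `GenomicRanges::findOverlaps`; the pairwise
  predicate is the direct `max(start) < min(end)` comparison. Both are
  checked against a per-base brute-force oracle in the tests.
* Undefined correlations require ≥ 3 complete pairs; nothing is imputed.
* Percentage rounding is half-up (not banker's) to one decimal, the
  convention for printed percentages.
* Reports are byte-deterministic: no timestamps in output files, one
  seed per stochastic call, fixed row/column orders.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
panels of ~210 regions × 50 cell types, cascade fixtures over 20 seeds,
one million permutation draws on a 707-line score table, exhaustive
enumeration up to `choose(12, 3)`, and 200-seed null-calibration sweeps
at 500 draws each. These sizes keep a full run in the tens of seconds
while leaving the stochastic assertions (3σ Monte-Carlo agreement,
mean-p calibration bands) comfortably powered.

## A worked run

```{r example}
st <- simulate_plexus_study(seed = 1)
rep <- run_cascade(st$regions, st$tad, st$matrix, st$truth$anchor_id,
                   st$activity_track, st$variants)
rep
glance(rep)
```

```{r essentiality}
ess <- simulate_essentiality(n_lines = 707, group_size = 8,
                             force_extreme = TRUE, seed = 1)
permutation_median_test(ess$scores, ess$group, n_perm = 1e6, seed = 2)
```

## Known limitations

* The accessibility matrix is a user input; the package does not ship a
  reference cell-type panel, and results depend on that panel's
  composition and comparability of scaling across cell types.
* Only SNVs are handled; indels and structural variants are out of scope.
* TADs are consumed as intervals; no Hi-C processing or TAD calling.
* The correlation linkage is association, not contact: corroboration by
  chromatin-contact data is the user's responsibility.
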