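---
title: "Methods: trajectory analysis of multi-omic passage series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of multi-omic passage series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senomics)
```

# The analysis problem

Serial passaging drives primary cells into replicative senescence, and the
molecular route there is a *trajectory*: features do not merely differ
between the first and last passage, they drift consistently in one
direction. `senomics` implements the downstream statistics for a design of
T ordered passages (default four, labelled P1, P3, P5, P7) profiled with
RNA-seq (4 replicates per passage), RRBS (3 independent replicate series)
and ATAC-seq (4 replicates at the first passage, 3 thereafter). All
coordinates are 0-based half-open throughout; BED is read natively and
1-based formats (the GTF subset) are converted on input. Chromosome names
are matched exactly — `normalize_chrom_names()` exists but is never applied
implicitly.

# Expression and signal trajectories

## Normalization and differential selection

`normalize_library_size()` computes median-of-ratios size factors: the
geometric mean across samples of each all-positive feature forms a
pseudo-reference, and a sample's factor is the median ratio to it. Size
factors are defined up to one common scale; the implementation agrees with
the standard reference implementation to numerical precision (checked in
the test suite). When no feature is positive everywhere — possible in very
sparse peak matrices — the function falls back to total-count scaling with
a warning rather than failing.

`test_differential()` contrasts every later passage against the reference
(default: the first) with a two-sided Welch t-test on `log2(x + 1)` of
normalized values, adjusts p-values by Benjamini–Hochberg *within each
contrast* across features, and selects a feature when any contrast passes
both adjusted p < `alpha` (default 0.05) and fold change > `min_fold` or
< 1/`min_fold` (default 2). The fold change is the ratio of normalized
group means with pseudocount 1, which keeps it defined for all-zero
features. Two deliberate design choices are worth stating:

* The test is a pluggable Welch t-test rather than a negative-binomial
  GLM. The selection semantics (any-vs-reference contrasts, BH within
  contrast, joint p/fold thresholds) are what downstream steps depend on;
  the `test_fun` argument accepts any two-sample test should a different
  engine be preferred.
* "Fold change > 2" is read as *any* passing contrast, matching the
  any-vs-reference selection; requiring it on all contrasts would conflate
  late-onset with progressive changes.

## The monotone rule

`classify_trajectory()` reduces a feature to its per-passage group means
and asks whether every adjacent difference is strictly positive (monotone
up) or strictly negative (monotone down); anything else — including flat
segments — is non-monotone. With the default `min_step = 0` the label
depends only on the ordering of the means, so it is invariant under any
strictly increasing transform; monotonicity is therefore assessed on
normalized group means rather than z-scores, to no loss. The strict
reading (flat fails) is the conservative interpretation of "monotonically
changed", and `min_step` can impose an effect-size floor per step.
RS-associated features (`select_rs_features()`) are the intersection of
differential selection and a monotone label; the up and down sets are
disjoint by construction.

## Modules

`cluster_modules()` z-scores each feature's group-mean profile (zero-variance
profiles map to the zero vector), then runs hierarchical clustering with
Ward linkage on Euclidean distances and cuts at k clusters. Defaults of
k = 6 for genes, 6 for DMR modules and 10 for peak modules mirror common
practice for this design; k is a user choice, as the underlying clustering
is unsupervised and the cut is a presentation decision. Duplicated
profiles have zero distance and always co-cluster.

# Methylome

Cytosine levels are `methylated / total` per site. For trajectory work,
calls are pooled per series × passage cell and a cytosine is retained only
when every cell reaches `min_coverage` (default 5) reads — below that,
levels are too quantized for deltas of 0.03 to be meaningful. No such
coverage rule is standard in the source protocols; 5 reads is this
package's floor, and incomplete cytosines are excluded rather than
errored.

`identify_dms()` implements the adjacent-delta rule: an increased DMS must
rise by strictly more than `delta_up = 0.05` at every adjacent passage *in
every series independently*; decreased DMSs mirror this with
`delta_down = 0.03`. The per-series reading is the strictest
interpretation of "in all 3 series"; a `series_mean` mode applies the rule
to the across-series mean trajectory instead, which is the natural looser
variant and is what the pipeline uses to propose candidate regions for
module work. Deltas compare raw (unsmoothed) levels and the comparison is
strictly greater-than, so a planted step of exactly 0.05 is never called.
Shrinking the thresholds can only grow the called sets, and the up and
down sets are always disjoint.

Region summaries (`region_mean_methylation()`) average the member cytosine
levels *unweighted*, matching the convention of averaging per-cytosine
levels within a binding site; a coverage-weighted variant sits behind
`weighted = TRUE`. Empty regions return `NA`, never 0. The TFBS trend test
(`tfbs_methylation_trend()`) computes one unweighted mean per binding site
per passage and applies a one-way ANOVA across passages, with p = 1 by
convention when all values are identical. DMR-to-gene mapping associates a
region with a gene when it overlaps the ±5 kb window around the TSS,
half-open, via the same window helper used for ±1 kb promoter annotation —
windows are symmetric and strand-agnostic, as the underlying definition
carries no strand qualifier.

# Accessibility

`build_atlas()` merges all per-sample peaks into their coverage union
(single-linkage; touching intervals form one region) and retains a region
when some passage group has strictly more than `min_fraction = 0.6` of its
replicates with an overlapping peak. "More than 60 %" is strict: 3/5
(0.60) fails, 2/3 (0.667) passes. Per-peak signal is the summed coverage
in the consensus interval, library-size scaled — a transparent
fragment-count proxy.

The MA analysis (`ma_high_coverage_counts()`) restricts to peaks with
overall mean normalized signal strictly above 800 and counts peaks
significantly more ("open") or less ("closed") accessible at the later
passage, reusing the differential machinery; significance-based coloring
was chosen over a bare ratio sign because the latter calls every peak at
any noise level. Note that with the pseudocount-1 fold change, an exact
2.0-fold change sits on the strict > 2 boundary; planted-recovery tests
therefore use effects clear of the threshold.

"Newly appeared at t" requires group presence (strict rule as above) at t
and absence at *every* earlier passage; re-gains after a loss are not
newly appeared. Disappearance is the mirror image and, by default, also
requires absence from t onward (`mode = "all_later"`); `mode = "at_t"`
relaxes that to absence at t only. A peak present at the very first
passage trivially "appears at t0" under the literal definition; reports
therefore count appearances at t ≥ 1.

Enhancers are the coverage intersection of H3K4me1 and H3K27ac peak sets —
exactly the double-positive definition. The promoter-shift comparison
(`promoter_shift_test()`) contrasts promoter-peak log2 fold changes of up-
or down-regulated gene classes against the all-genes class with Welch
t-tests
and reports the per-class ECDF values; classes that map to fewer than two
promoter peaks raise an error naming the class.

# TF regulation

`scan_pwm()` scores each offset as the sum of `log2((p + 1e-3)/bg)` over
motif positions and calls a hit at ≥ 80 % of the maximum attainable score
(a conventional threshold, exposed as `min_score_fraction`). Both strands
are scanned via the reverse-complemented matrix, with minus-strand hits
reported in forward coordinates; a palindromic motif would otherwise
produce mirrored duplicates, so hits identical in interval and score are
reported once on the plus strand.

`motif_enrichment()` counts a region once per motif regardless of hit
multiplicity (region-level semantics), computes the upper hypergeometric
tail P(X ≥ k) with the full peak set as background, adjusts across motifs
by BH and ranks. A calibration subtlety documented here because the test
suite relies on it: the exact tail p of a discrete count is *super*-uniform
under the null (P(p ≤ x) ≤ x), so a raw Kolmogorov–Smirnov uniformity
check fails at any feasible region count no matter how correct the
implementation. Calibration is therefore verified on the randomized
transform p − U·P(X = k), which is exactly Uniform(0, 1) under the null,
together with a guard that the raw p is not anti-conservative.

Footprint profiles average forward- and reverse-strand coverage per
position over ±100 bp windows around each hit, orienting minus-strand hits
by reversal before averaging so asymmetric footprints are not washed out
(flanks are measured from the motif edges; a centred mode can be obtained
by widening the hit intervals). The activity statistic is transparent:
depth = mean(flank) − mean(body), and the activity delta between passages
is the difference of depths, positive when occupancy deepens. This
replaces bias-corrected protection scores on purpose — Tn5 sequence-bias
modelling is out of scope — and behaves correctly on the generator's
planted dips.

`classify_tf()` applies the published three-rule partition on (CD, COI):
pioneer iff CD > 0.45 and COI > 4; settler iff CD > 0.45 and COI ≤ 4;
migrator otherwise. The three strict inequalities leave the boundary
values themselves undefined, so boundaries fall to the lesser class by
default (`boundary = "greater"` flips this). CD and COI are inputs from an
upstream footprint model; their computation is explicitly not reimplemented
here.

# The synthetic study

`sim_config()` fixes the study conditions: 4 passages; expression with 4
replicates, 5,000 genes, 200 planted monotone-up and 200 monotone-down at
one doubling per step, NB dispersion 0.1, log-normal baselines; methylome
with 3 series, 2,000 cytosines, 60 planted increasing (+0.10/step from
0.10) and 60 decreasing (−0.04/step from 0.60), binomial reads at mean
depth 30 (an `exact` mode emits rounded expectations at depth 10,000 for
noise-free recovery checks); accessibility with replicates 4/3/3/3, 60
non-overlapping peaks of 400 bp (half centred on gene promoters), 8
scheduled appearances and 8 disappearances, presence probability 0.95 when
scheduled present and 0.05 otherwise (chosen so the strict > 60 % rule is
informative at 3–4 replicates), flat peak enrichment over a unit
background with 2 % block noise, an embedded 10-bp consensus motif in
every appearing peak and a subset of stable peaks, and a multiplicative
50 % footprint dip applied per sample with probability equal to the
passage's bound fraction (0.2, 0.4, 0.6, 0.8).

Binomial (not beta-binomial) methylation noise is the default — a simpler
null that makes exact-recovery statements crisp — with overdispersion left
to future work. All generators are pure functions of the configuration:
one seed per run, sub-streams derived by fixed offsets so adding a
generator does not perturb the others, and identical seeds give
byte-identical files (FASTA/BED/bedGraph/TSV plus a manifest JSON).

What the generator does *not* emulate: read-level artifacts (alignment,
duplicates, Tn5 insertion bias), CpG context, correlated replicate
structure, and realistic genome composition. Passing tests therefore
demonstrate that the statistics implement their definitions and recover
planted truth under idealized noise — not that any particular biological
dataset will yield similar counts.

Problem sizes for the shipped checks were chosen to make each property
measurable in seconds-to-minutes on one core: 1,000-cytosine oracle
comparisons, 5,000-gene recovery runs over two seeds, ten simulated
studies for event detection and footprint deltas, 300–1,000 enrichment
resamples, and two full pipeline executions for the byte-identity check.

# Numerical and degenerate-input conventions

* Readers reject invariant-violating records (end ≤ start, m > n,
  negative counts) with line numbers rather than coercing.
* A feature with zero variance in both groups gets p = 1 when means agree
  (p = 0 otherwise); a constant-zero feature has log2 fold change 0 via
  the pseudocount.
* Empty methylation regions are `NA`; ANOVA on identical values returns
  p = 1; hierarchical clustering ties are resolved by the deterministic
  ordering of `stats::hclust`, and duplicated profiles always co-cluster.
* `pipeline_config()` validates every parameter and raises a classed
  condition (`senomics_config_error`) naming the offending key; the
  pipeline's stage functions degrade gracefully (e.g. the promoter-shift
  comparison reports `NA` when a gene class maps to fewer than two
  promoter peaks at small atlas sizes).

# Known limitations

The differential engine is a Welch test, not a count GLM with dispersion
shrinkage — adequate at 3–4 replicates for the fold changes the monotone
rule targets, but less powerful for subtle effects. DMR discovery here is
a naive same-direction merge of DMS calls intended as plumbing, not a
smoothing-based DMR test; model-based DMR intervals should be supplied as
inputs where available. PWM scanning is exhaustive and single-threaded,
sized for targeted region sets rather than whole mammalian genomes. CD and
COI values are consumed, never computed.
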