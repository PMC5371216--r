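---
title: "Methods: differential abundance across a dehydration-rehydration cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential abundance across a dehydration-rehydration cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desiccatome)
```

## The analysis this package implements

Resurrection plants survive the near-complete loss of water from their
vegetative tissue and resume metabolism on rewatering. A standard experiment
samples leaf tissue across a drying-rewatering series -- full hydration
(`HYD`, ~96% relative water content), dehydration stages at 80, 60, 40 and
30% RWC, the desiccated state (`DRY`, ~11% RWC), and rehydration time points
12 h and 24 h after rewatering -- and asks which transcripts and metabolites
change, when, and in which coordinated patterns. This package implements the
full statistical path from a normalised expression matrix (and a metabolite
relative-abundance table) to significantly differentially abundant
transcripts (SDATs), expression clusters, significance-masked fold-change
tables, cross-platform validation, and hormone quantification. A
synthetic-data generator with planted ground truth drives every stage, so
the entire analysis is testable without any external data.

Relative water content itself is `rwc(Fwt, FTwt, Dwt) =
(Fwt - Dwt) / (FTwt - Dwt)`: fresh weight relative to full-turgor weight,
both in excess of dry weight.

## Probe summarisation

Expression arrays carry several short probes per gene. The processing path
is the RMA-style sequence: quantile normalisation across arrays, log2
transform, then a per-gene median polish of the probes x arrays block,
jointly across all arrays; the per-array expression measure is the overall
effect plus the array (column) effect.

Two numerical choices are explicit:

* **Quantile normalisation ties.** Each value is replaced by the mean over
  columns of the values sharing its rank; tied values receive the average of
  the reference values over the tied ranks (`rank(ties = "average")`
  semantics). With no ties, all columns share an identical multiset of
  values afterwards.
* **Median polish stopping rule.** Row and column medians are swept
  alternately until the largest absolute change in any fitted effect during
  a full sweep falls below `tol` (default `1e-6`) or `max_iter` (default 10)
  sweeps have run. The sweep is written directly so this stopping rule is
  exactly the documented one; the tests cross-check the fitted effects
  against `stats::medpolish`.

Probe-specific convolution background correction is deliberately not
modelled: it requires parameters that the statistical pipeline downstream
does not depend on. A simple percentile-floor background is available behind
`summarize_probes(background = "floor")` for intensity matrices with a
noise floor; the default is a no-op.

## The replicate-cleansing rule

Each gene x condition cell holds a biological triplicate of log2 expression
values. The cleansing rule flags gross single-measurement artifacts:

1. A triplicate whose coefficient of variation (CV = sd/mean, sample sd)
   exceeds **0.5** is scrutinised.
2. Within a scrutinised triplicate, a replicate more than **one sample
   standard deviation** from the triplicate mean (strict inequality) is a
   candidate single outlier. For three values the standardised deviation
   `|x_i - mean|/sd` can never exceed `(n-1)/sqrt(n) = 2/sqrt(3) = 1.1547`
   (`max_abs_z_bound(3)`), and since the squared standardised deviations
   always sum to exactly 2, **at most one** replicate of three can ever pass
   the 1-sd cut -- the candidate is unambiguous. The candidate is dropped
   when its removal *moderates* the CV, which this package defines as the
   remaining pair's CV falling to 0.5 or below (the scrutiny threshold
   itself; the original description leaves "moderated" undefined).
3. A scrutinised triplicate with no removable outlier (or one whose removal
   does not moderate the CV) is excluded entirely when its CV exceeds
   **0.75**, and otherwise kept with a flag.
4. Cells with non-positive mean have no meaningful CV on the log2 scale and
   are kept unfiltered with a warning record.

All three thresholds (`cv_scrutiny = 0.5`, `cv_hard = 0.75`, `z_cut = 1`)
are arguments throughout. The decision log lists every triplicate with its
CV, standardised deviations, action and trigger, and the summary reports the
fraction of triplicates scrutinised, single-outlier exclusions and complete
exclusions -- the counts a study of this design reports.

## SDAT designation

The dehydration treatments are ordered by water content and the rehydration
treatments by time, so the series are analysed as two condition groups:
dehydration (`HYD, 80, 60, 40, 30, DRY`) and rehydration (`DRY, R12, R24`).
Per group and per gene, a classic one-way fixed-effects ANOVA runs on the
cleansed replicate values (groups may be ragged, sizes 2 or 3, after
cleansing). A gene is excluded from a group when any condition retains fewer
than two values. Degenerate inputs have a defined contract: all groups
constant and equal gives F = 0, p = 1; zero within-group variance with
unequal means gives p = 0 (this makes zero-noise simulations exact).

P-values are Benjamini-Hochberg adjusted **within each group across all
genes tested in that run** -- the two groups are corrected separately, since
they are analysed separately; the reported SDAT set is the union. Genes with
adjusted p < 0.05 are SDATs and receive a Tukey post-hoc test to determine
under which pairwise comparison each is differentially abundant. Because
cleansing makes group sizes unequal, the Tukey-Kramer standard error
`sqrt(MSW/2 * (1/n_i + 1/n_j))` is used, with p-values from the studentised
range distribution (`ptukey`) at the ANOVA residual degrees of freedom.

## Threshold-validity clustering

Clusters of SDAT profiles (per-condition means of the cleansed values) are
defined by a validity criterion, not a dendrogram cut: a set of profiles is
a cluster only if its **average pairwise Pearson correlation is at least
0.85**. The agglomeration is greedy best-merge: at each step the merge
yielding the highest average pairwise correlation in the merged set is
performed, provided that average stays at or above the threshold; the
procedure stops when no acceptable merge remains, and the criterion is
re-asserted on every emitted multi-profile cluster before returning. Ties
are broken towards the candidate containing the lexicographically smallest
gene id, so output is deterministic. Constant profiles have no defined
correlation and become singletons. This direct optimisation of the validity
criterion was chosen because a linkage-based cut does not guarantee the
average-pairwise property the criterion states.

Rehydration profiles have only three points; correlations over three values
are weakly informative, so rehydration clustering is supported but flagged
low-confidence in the pipeline log, and the cluster outputs cover the
dehydration series.

## Metabolite analysis

Metabolite relative abundances (seven groups -- `HYD, 60, 40, 30, DRY, R12,
R24` -- with six replicates each) are compared by Welch's t-test on
log-transformed values for the five standard comparisons `DRY/HYD, R12/DRY,
R24/DRY, R12/HYD, R24/HYD`. The natural log is used; the base does not
affect t, df or p. No multiple-testing correction is applied to metabolite
p-values: significance is per-comparison at p < 0.05, matching how such
tables are conventionally reported. Fold changes are **linear ratios of
group means**, and a table cell is blank (NA) when the comparison is not
significant -- a blank means "no significant difference", never "not
measured".

Each metabolite's rehydration trajectory is classified purely from the five
direction flags (up / down / none), by a top-down decision chain:
`increased_further` (up vs DRY and up vs HYD during rehydration),
`remained_elevated` (up vs HYD, no change vs DRY), the two depleted mirror
classes, `returned_to_control` (a significant DRY/HYD change with no
significant R24/HYD difference), else `declined_toward_control`. The chain
is total and mutually exclusive over all 3^5 flag combinations, which the
tests verify exhaustively.

## qPCR concordance

Relative quantification uses the delta-delta-Ct contrast with amplification
efficiency fixed at 2: Ct values are averaged over replicates within gene x
condition, target minus reference differences are contrasted against the
hydrated calibrator, and the log2 ratios for `80/HYD ... DRY/HYD` are paired
with the array log2 ratios. Concordance is summarised by the OLS regression
of array on qPCR ratios (R^2 and a zero-slope t-test) plus the Spearman rank
correlation with average ranks on ties. The reference gene is explicit: no
default gene name is assumed, the generator emits a designated stable
reference and the interface requires its name.

## ABA quantification

The calibration curve is an ordinary least-squares fit (free intercept) of
the analyte / internal-standard peak-area ratio against concentration over
the seven standards 0.5, 1, 2, 5, 10, 25 and 50 ng/ml. The endogenous
analyte present in the spiked control matrix is handled by subtracting the
mean control area ratio from every standard before the fit -- an additive
correction, the simplest model consistent with "accounting for" the
endogenous contribution. Unknowns are back-calculated by inverting the line,
floored at zero with a warning when the ratio falls below the intercept, and
converted to tissue content as `conc x volume / dry mass` (defaults: 80 ul
reconstitution volume, 20 mg dry tissue, giving ng per g dry weight).

## Enrichment

Term over-representation in an SDAT list uses the upper-tail hypergeometric
probability `P[X >= k]` per term against the assayed-gene universe, with
Benjamini-Hochberg adjustment across the tested terms and a 0.05 adjusted-p
threshold. Terms are flat gene sets supplied as GMT (read via `fgsea`);
ontology-graph propagation is out of scope.

## The synthetic-data generator

`sim_config()` holds the study conditions: 8 conditions x 3 replicates for
expression, 7 groups x 6 replicates for the metabolome. Its defaults are
fixed package choices, not tuning knobs:

* **Archetype profiles** (`ARCHETYPE_PROFILES`) are fixed log2 deviations
  from a per-gene baseline, one shape per predominant cluster pattern of a
  dehydration series: rise-and-plateau, peak-at-30%-RWC, monotone decline,
  dip-then-rise-to-dry, and rise-then-crash, plus a constant null. The exact
  values were chosen so that the shapes are visually faithful to those
  cluster patterns *and* mutually separable under the clustering criterion:
  the between-archetype correlation over the six dehydration conditions is
  at most 0.61, and a greedy merge of two equal-size clusters with
  cross-correlation r is accepted only when (1+r)/2 >= 0.85, i.e. r >= 0.70.
  One consequence is that the rise-then-crash shape rises somewhat faster
  early in drying than its real counterpart; the crash on desiccation is its
  distinguishing feature.
* **Archetype composition** uses a largest-remainder allocation of the
  requested proportions (default: 50% null, 10% each pattern), then
  shuffles labels. The planted composition therefore matches the weights
  exactly, which keeps cluster sizes balanced -- relevant because the
  average-pairwise criterion will absorb a very small cluster into a much
  larger one (for a size-n cluster and a singleton the merged average is
  `(n-1+2r)/(n+1)`, above 0.85 for n >= 13 regardless of r).
* **Baselines and noise.** Per-gene baseline log2 abundance is uniform on
  (7, 8); replicate noise is Gaussian with sd 0.2 log2 units. With the
  archetype amplitudes of 1.4-2.4 log2 units this puts the planted
  effect-to-noise ratio at 7-12, the regime in which the recovery tests
  demand sensitivity >= 0.9.
* **Outliers.** Each triplicate independently receives at most one planted
  outlier with probability 0.1 (the fraction of triplicates the original
  cleansing step scrutinised), an additive shift of +-13 log2 units with
  random sign. The CV > 0.5 trigger on log2 values is scale-dependent: a
  shift of magnitude s on a triplicate with mean m raises the CV above 0.5
  for *both* signs only when `s/3 < m < 0.8215 s`. With condition means
  spanning roughly 4.6-10.2, s = 13 places essentially every planted
  outlier inside that window, which is what makes the ">= 95% of planted
  outliers flagged" recovery test meaningful rather than vacuous.
* **Metabolites** are lognormal: baseline log2 abundance uniform on (3, 10),
  planted trajectory patterns scaled by `metab_effect_log2` (default 1, a
  two-fold peak effect), log-scale Gaussian noise with sd 0.25 -- lognormal
  because the analysis log-transforms before testing.
* **qPCR generator.** True per-gene log2 ratios are drawn with sd 2;
  replicate Ct noise is 0.05 cycles; the paired "array" ratios equal the
  realised qPCR ratios plus Gaussian noise whose variance is set from the
  target R^2 (`var(q)(1-R2)/R2`), so the achieved R^2 of a draw fluctuates
  around the target and equals 1 exactly when the target is 1. The default
  target, 0.843, is the concordance level the package's validation stage is
  designed to detect.
* **Calibration standards** respond linearly (default slope 0.2 area-ratio
  per ng/ml, intercept 0.01) with additive Gaussian ratio noise.

Identical seeds give bit-identical output everywhere.

### What the generator does not emulate

Probe-level hybridisation physics, scanner artifacts, spatial effects,
cross-hybridisation, and sequence content are not modelled; the generator
emits gene-level (or, for the summarisation tests, synthetic probe-level)
values with clean Gaussian noise. Real replicate noise is heavier-tailed and
intensity-dependent, real outliers are not all single-replicate additive
shifts, and real cluster structure is not a small set of exact shapes.
Passing recovery tests therefore demonstrates that the statistical machinery
is implemented correctly and is well calibrated under its own assumptions --
not that those assumptions hold for any particular real dataset.

## Problem sizes and runtime choices

The recovery analyses run at 1,000 genes x 24 arrays (and 200-500
metabolites), sizes at which every stage completes in seconds while leaving
the Monte-Carlo error of the recovery estimates small; the property tests
over random triplicates use 10^6 draws. These sizes are package choices made
once; all functions scale to full array sizes (tens of thousands of genes)
with linear cost in genes.

## Known limitations

* The cleansing rule is defined for triplicates; other replicate counts are
  rejected rather than generalised (the z-bound generalises, the published
  thresholds do not obviously).
* The CV-based trigger is scale-dependent by construction; it is faithful to
  the described procedure but will behave differently on data stored on
  other scales.
* The greedy validity clustering guarantees the average-pairwise criterion
  but, like the criterion itself, can place a profile in a large cluster it
  correlates with only weakly (the criterion bounds the average, not the
  minimum, pairwise correlation).
* Welch tests on n = 6 log-abundances are only as robust as the lognormal
  assumption; no imputation of platform dropouts is attempted beyond
  allowing groups down to n = 2.
* Amplification efficiency is fixed at 2 in the delta-delta-Ct contrast;
  efficiency-corrected variants are out of scope.
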