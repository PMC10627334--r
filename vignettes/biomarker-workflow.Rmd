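---
title: "From label-free LC-MS feature matrices to trait biomarkers: models and design choices"
author: "wheatlma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From label-free LC-MS feature matrices to trait biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatlma)
```

## The problem

Late-maturity alpha-amylase (LMA) is a genetic defect of bread wheat in which
a temperature shock during grain development triggers synthesis of high-pI
alpha-amylase, degrading starch and failing the industry's falling-number
standard. The enzymatic activity (Ceralpha units per gram of flour, U/g) can
be assayed, but the proteomic response behind it is what breeders would like
to select on. The setting this package addresses is therefore: a large
label-free LC-MS1 experiment quantifies tens of thousands of peptide clusters
(isotope-grouped features with retention time, m/z, neutral mass and charge)
across thousands of flour samples, each sample annotated with a single
skewed, partially missing quantitative trait; find the peptides whose
abundance tracks the trait.

Two properties of such cohorts drive the whole design. First, a months-long
acquisition run leaves strong technical structure in the intensities:
sample-loading differences, post-digestion variation, a slow decay of mass
analyser sensitivity between maintenance events, and step changes when the LC
column, the mass calibration or the source capillary change. Second, the trait
is extremely skewed — most samples sit below 0.2 U/g with a thin tail reaching
about 8 U/g — so naive regression or subsampling is dominated by the bulk.

## The processing model

### Normalization cascade

Intensities pass through three steps in a fixed order, each reported with
per-sample factors and per-feature QC coefficients of variation:

1. **Flour weight** — each wheat sample is scaled by `nominal / weight`
   (nominal 20 mg, tolerance about 1%), cancelling loading variation.
   Pooled-QC injections carry no flour weight and are left unscaled.
2. **Internal standard** — each sample is divided by its IS intensity over
   the cohort median; the spiked IS absorbs post-digestion variation.
3. **Injection-order drift** — per feature, the QC intensities (one pooled QC
   every 48 injections) are interpolated piecewise-linearly across injection
   order, the curve is normalized to the feature's median QC level, and
   divided out. Constant extrapolation is used beyond the terminal QCs, and a
   feature observed in fewer than half of the QCs falls back to a global
   curve (per-QC median of feature-wise ratios), flagged in the report. The drift algorithms
   built into commercial processing suites are proprietary and unpublished;
   QC-anchored interpolation is the standard label-free remedy and is exact
   at the anchors, which the tests exploit.

The order is enforced through a stage tag on the matrix
(`raw -> weight -> is -> drift -> corrected -> z`); running a step out of
order is an error rather than a silent wrong answer. No step imputes: missing
cells stay missing.

### Technical-factor quantification and removal

Three categorical factors describe the maintenance state of the instrument:
LC column (4 levels), mass calibration (6 levels), source capillary
(2 levels). Their multivariate impact is quantified by ANOVA simultaneous
component analysis: per factor, the effect matrix of level means of the
(feature-centred, zero-imputed) data, its sum of squares as a fraction of the
total, and a permutation p-value from shuffling that factor's labels
(`(1 + #exceedances) / (n_perm + 1)`, 100 permutations by default, so the
smallest attainable p is 1/101).

Factors are then removed by fitting, independently per feature, the additive
fixed-effect model

$$ Y_{ijkl} = u + \mathrm{Column}(i) + \mathrm{MassCal}(j) + \mathrm{Cap}(k) + e_{ijkl} $$

by ordinary least squares and keeping the residuals as the corrected data.
Sum-to-zero constraints make the level effects identifiable (the model as
stated is over-parameterised; any constraint gives the same residuals).
Unlike the decomposition step, the per-feature fit drops missing cells rather
than zero-imputing them — zero-imputation before OLS would bias the level
effects toward zero intensity — and this asymmetry is deliberate and flagged.
Samples with incomplete factor metadata cannot be corrected; they pass
through centred on the feature mean and are listed in the output.
Residuals of complete observations are exactly orthogonal to every
factor-level indicator, which is the property the acceptance checks assert.

Rows are finally z-transformed (mean 0, SD 1 over finite values, denominator
n − 1; constant rows become zeros and are flagged). A one-sample
Kolmogorov–Smirnov statistic against the standard normal documents that the
z-transform reduces, but does not abolish, the skew of the pooled
distribution.

### Trait handling

The trait enters the analysis on the **standardized inverse** scale: among
ln, log2 and inverse, the inverse is the transform that brings the skewed
activity closest to normality, and standardizing it lets it sit beside
z-scored peptides. One consequence deserves emphasis because it affects every
sign in the package: the inverse reverses order, so a peptide that
accumulates with high activity is *negatively* correlated with the
standardized-inverse trait, and the trait pseudo-row itself has a negative
two-bin effect size.

*Unbiased subset.* All samples at or above 0.17 U/g (the "tipping point"
between sound and unsound grain) are kept and an equal-sized seeded random
draw of below-threshold samples joins them, giving a balanced set for the
supervised and clustering analyses.

*Imputation.* Missing trait values are predicted by univariate PLS regression
(NIPALS) of the trait on the peptide matrix, using features with at least 20%
valid values (row-mean imputed) and 20 latent factors. Validation holds out
samples spanning the trait range — stratified over ten equal-width strata —
refits, and reports R² overall and above/below 0.17 U/g. Three numerical
guards apply: the requested hold-out (default 179, the full-scale choice) is
capped at a quarter of the training samples; the number of latent factors is
capped at one per ten training observations (at the full scale neither cap
binds); and predictions are clamped to the training range, with negatives set
to zero and counted. When the imputed trait later joins the inverse
transform, zeros are floored at the cohort's smallest measured activity —
the inverse of an arbitrary small floor would otherwise be an extreme
outlier on the standardized-inverse scale and would dominate every Pearson
statistic downstream.

*Pseudo-feature.* The standardized-inverse trait is appended as row
`Cluster_AAA`. Clustering methods can then *group* peptides with the trait,
and the screens have a built-in positive control: `Cluster_AAA` must come
out with correlation 1 and regression q-value 0.

### Screens and the union selection

* **PLS-VIP** — a NIPALS PLS1 fit of the standardized-inverse trait on the
  unbiased samples (3 latent factors, 10% valid values, row-mean imputation).
  Variable importance in projection is
  $\mathrm{VIP}_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}$ with unit-norm
  weight vectors, so mean(VIP²) = 1 identically; VIP > 1 defines the feature
  subset handed to the clustering methods (with the trait row always kept).
* **SOM** — a 6 × 8 batch self-organising map under positive correlation
  distance (1 − Pearson r; profiles are row-standardized so the distance is a
  dot product), Gaussian neighbourhood shrinking linearly from half the grid
  diagonal to 1 over 50 iterations, codebooks initialised from a seeded
  feature sample. Best-matching-unit ties break to the lowest unit index.
* **k-means** — k = 20 under the same distance with mean centroids, 50
  iterations, and ten seeded restarts keeping the run with the smallest total
  within-group distance (single starts land in visibly poorer local optima).
* **Divisive HCA** — recursive 2-means bisection: the farthest pair of
  members initialises each split (deterministic, no seed), children are laid
  out depth-first with the lowest-index child first, and clusters at or below
  `min_size` (default 20) become leaves. Leaf order indexes the tile plot;
  terminal-cluster membership defines the trait neighbourhood. Ward linkage
  is not meaningful for a divisive tree; the agglomerative Ward variant is
  used only for ordering samples in the heatmap.
* **Correlation** — per-feature Pearson r against the trait row over
  pairwise-complete observations (minimum overlap 10), flagged at signed
  r ≥ 0.15. The squared-correlation reading (r² > 0.15) is available as a
  switch; the signed form is the default because the negative tail is
  deliberately excluded from this criterion.
* **Regression** — per-feature OLS on the transformed trait with a two-sided
  t-test for the slope and Benjamini–Hochberg q-values across all tested
  features; q < 0.05 flags a feature. Constant or under-observed features are
  excluded from the BH family rather than given fake p-values.

A biomarker is any feature satisfying **at least one** of the five criteria
(SOM cell, k-means group or HCA terminal cluster shared with `Cluster_AAA`;
correlation; regression). All five flags and the underlying statistics are
recorded per feature, so the union is auditable, and relaxing any single
threshold can only grow the set.

### Profiling and identity linking

Samples are sorted by trait and cut into 8 near-equal bins (remainder to the
earliest bins: 3,990 samples give six bins of 499 and two of 498) for
per-feature mean profiles, or into 2 bins at 0.17 U/g on the unbiased set for
a pooled-variance two-group t-test with directed effect size
(mean(bin 2) − mean(bin 1); Welch is a switch). A bootstrap-stabilized p
(mean analytic p over seeded balanced subsamples, 10 by default) is reported
alongside, but the analytic p is primary — "balanced bootstrap" settings in
commercial suites do not pin down a reproducible resampling scheme. The volcano table joins
effect sizes, p-values and selection flags; the heatmap column order comes
from agglomerative Ward clustering of sample profiles under correlation
distance.

MS1 quantitative clusters are matched to MS2 identification clusters within
20 ppm on m/z and mass and 1 minute on retention time; among candidates the
combined normalized distance decides, greedily and one-to-one (ties to the
lowest indices), so every quantity keeps at most one identity. An
absolute-tolerance mode covers the alternative reading of the matching rules.
Identified peptides typically hit many homoeologous accessions (hexaploid
wheat's A/B/D subgenomes); the wide peptide-by-accessions table is expanded
to long form with per-accession and per-peptide counts.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the *statistical structure* the pipeline assumes:

* trait from a two-component log-normal mixture — bulk 0.88 · LN(log 0.105,
  0.25), tail 0.12 · LN(log 0.9, 0.8), truncated to [0.01, 10] U/g —
  calibrated so the expected share below 0.2 U/g is 0.88, matching the
  measured cohort; a 5.4% trait-missing fraction;
* log-normal baseline feature abundances; a flour-weight loading multiplier;
  one precisely measured internal-standard cluster; pooled QCs every 48
  injections with reduced noise and no biomarker signal;
* multiplicative technical effects: per-level factor offsets (SD 0.3 log
  units) and geometric within-interval sensitivity decay (0.1–0.4% per
  injection, reset at each mass-calibration event), both modulated by a
  per-feature sensitivity in U(0.25, 1.75) — a shared effect with identical
  per-feature scaling would be removed entirely by the IS step, which the
  real data contradict;
* planted biomarkers: 60 features (half up, half down) whose log-intensities
  shift linearly with the standardized-inverse trait, slopes of magnitude
  0.5–1 log units per SD;
* missingness censored at random with a logistic rate in log-intensity, so
  low-abundance features are preferentially missing and valid-value filters
  are exercised.

Defaults are a desk-scale cohort of 300 wheat samples × 2,000 features; the
full-scale geometry (3,990 × 32,336) is supported but the packaged analyses,
tests and drivers all run at desk scale (the tests complete in a few minutes
on one core). What the generator does **not** emulate: inter-feature
correlation beyond the shared technical component (an optional block
structure was considered, but no defensible default exists for homoeolog
redundancy, so none is planted); peptide sequences, spectra or chromatograms;
non-monotone drift within a maintenance interval; and informative (signal-
dependent) trait missingness. Passing recovery tests therefore demonstrate
that the chain of estimators is correct and well-calibrated under the stated
structure, not that real cohorts satisfy that structure.

Desk scale also changes what the thresholds mean. With 294 analysed samples
the null distribution of a Pearson correlation has SD ≈ 0.058, so the fixed
r ≥ 0.15 criterion admits roughly half a percent of null features — at the
full scale (null SD ≈ 0.016) it admits essentially none — and the clustering
neighbourhoods are computed on an unbiased subset of only ~84 samples, where
null correlations of 0.2–0.3 arise by chance. Union selection on the default
cohort consequently recovers every planted biomarker (and its direction) but
carries those structural false positives with it; the recovery metrics
printed by the pipeline quantify this honestly rather than hiding it.

## Numerical choices and degenerate inputs

* Sum-to-zero contrasts for the fixed-effect fit; rank-deficient designs are
  fitted by pivoted QR and flagged per feature.
* SD denominator n − 1 throughout; constant rows z-transform to zeros with a
  flag; a constant feature is excluded from the regression family.
* Correlation-distance engines operate on centred unit-norm profiles; rows
  with zero spread map to the zero profile.
* Ties: best-matching unit, k-means assignment and 2-means initialisation
  break to the lowest index; equal-distance match candidates break to the
  lowest MS1 then MS2 index.
* Every stochastic step (generator, permutation tests, subset draws,
  hold-out draws, restarts, bootstrap) takes an explicit integer seed and
  restores the caller's RNG state; the pipeline derives stage seeds from one
  master seed and records them in the manifest, and identical configurations
  yield byte-identical output files.
* The K-S p-value uses the asymptotic Kolmogorov series; at the pooled sizes
  involved the statistic D, not p, is the quantity of interest.

## Known limitations

* The drift model and its corrector share the "piecewise-smooth between QCs"
  assumption; drift that reverses between two QCs is invisible to both.
* PLSR imputation of a trait that enters the features through its inverse is
  intrinsically nonlinear in the raw activity; hold-out R² on the raw scale
  is accordingly modest at desk scale and strongly asymmetric (better above
  0.17 U/g than below, where the dynamic range is small against noise); the
  asymmetry is inherent to imputing a threshold-dominated trait, not a
  desk-scale artifact.
* With a single quantitative trait there is no external ground truth for
  selection thresholds; the union rule is a screening device, and its
  desk-scale false-positive load is characterized above.
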