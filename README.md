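# wheatlma

Trait-to-biomarker discovery for large label-free LC-MS peptide matrices,
motivated by the wheat late-maturity alpha-amylase (LMA) problem.

A months-long label-free LC-MS1 run quantifies tens of thousands of peptide
clusters across thousands of flour samples, each annotated with one skewed,
partially missing quantitative trait (alpha-amylase activity in U/g). Between
the raw intensities and a defensible biomarker list stand several confounders
— sample loading, post-digestion variation, instrument drift, maintenance
events — and several statistical steps that must agree with each other. This
package implements that chain end to end, for statisticians and proteomics
analysts who want each step testable in isolation:

* **Synthetic cohorts with ground truth** — a seeded generator emulating the
  study structure (skewed trait mixture, QC injections every 48 samples,
  internal standard, factor offsets with 4/6/2 levels, geometric
  injection-order drift, planted trait-associated peptides, abundance-biased
  missingness) for parameter-recovery testing.
* **Normalization** — flour-weight scaling, internal-standard scaling, and
  QC-anchored piecewise-linear drift correction, in enforced order.
* **Correction** — ASCA (per-factor variance fractions with permutation
  p-values) and per-feature OLS residualization of
  `Y = u + Column(i) + MassCal(j) + Cap(k) + e`, then row z-transform and
  Kolmogorov–Smirnov diagnostics.
* **Trait handling** — inverse-family transforms, balanced ("unbiased")
  subsampling at 0.17 U/g, PLS-regression imputation of missing trait values
  with stratified hold-out validation, and incorporation of the standardized
  inverse trait as pseudo-feature `Cluster_AAA`.
* **Discovery** — NIPALS PLS1 with VIP scores
  (`VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)`, mean VIP² = 1),
  batch SOM (6×8), correlation-distance k-means (k = 20), divisive 2-means
  HCA, per-feature correlation (signed r ≥ 0.15) and regression screens with
  Benjamini–Hochberg q-values (q < 0.05), and the five-criterion union
  selection.
* **Profiling** — 8-bin and 2-bin trait-sorted mean profiles, pooled-variance
  two-group tests with directed effect sizes, volcano tables, Ward-ordered
  heatmap layouts.
* **Identity linking** — one-to-one matching of MS1 quantitative clusters to
  MS2 identification clusters within 20 ppm (m/z, mass) and 1 min (RT), and
  wide-to-long expansion of peptide-to-accession tables.

The methods vignette (`vignettes/biomarker-workflow.Rmd`) documents the
models, defaults, numerical guards, and what the synthetic cohorts do and do
not emulate.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
desk-scale cohort (300 wheat samples × 2,000 peptide clusters, 60 planted
biomarkers, seed 42) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_normalize_correct.R
Rscript analysis/03_trait_and_discover.R
Rscript analysis/04_profile_and_link.R
```

which prints, step by step:

```
cohort: 2000 features x 306 samples ( 6 QCs )
planted biomarkers: 60 ( up: 30 / down: 30 )
trait: 284 measured, 87.3% < 0.2 U/g, range 0.05-4.59 U/g

ASCA variance fractions and permutation p, before correction:
     factor variance_fraction          p
1 lc_column        0.15995205 0.00990099
2  mass_cal        0.18991012 0.00990099
3 capillary        0.05986767 0.00990099
...and on the residuals:
     factor variance_fraction p
1 lc_column      1.402654e-33 1
2  mass_cal      5.967758e-33 1
3 capillary      6.315195e-34 1
K-S D: corrected 0.270 -> z-transformed 0.082

unbiased subset: 84 samples
trait missingness: 16 of 300 = 5.3 %
imputation: 16 values imputed, hold-out R2 0.15 (high 0.09)
neighbourhood sizes (som/kmeans/hca): 3 40 13
selected biomarkers: 80
recovery vs truth: precision 0.75 recall 1.00 direction 1.00

two-bin direction of the 57 profiled biomarkers: 27 up / 30 down
MS1-MS2 matching: 1199 of 1999 clusters = 60 %
```

Reading the output: all three injected technical factors are significant
before correction (p = 1/101, the permutation floor) and carry essentially
zero variance afterwards; the z-transform roughly thirds the K-S departure
from normality; every planted biomarker is recovered with its direction
(recall 1.00), while the fixed screening thresholds admit a known, quantified
share of null features at this cohort size (precision 0.75) — the vignette
discusses why that is a property of the thresholds at desk scale, not of the
estimators. `Cluster_AAA`, the trait inserted as a pseudo-feature, comes out
of the screens with correlation 1 and q-value 0, as it must.

The same run is available in one call:

```r
library(wheatlma)
run <- run_pipeline(pipeline_config(seed = 42), out_dir = "results/run")
run$recovery
```

Identical configuration and seed give byte-identical outputs and manifest.

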