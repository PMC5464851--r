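---
title: "Methods: miRNA expression signatures of pediatric AML subtypes"
author: "miRsigAML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA expression signatures of pediatric AML subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRsigAML)
```

## Scope and model

Pediatric acute myeloid leukemia (AML) splits into recurrent (cyto-)genetic
subtypes — *MLL*/11q23 rearrangements, t(8;21)(q22;q22), inv(16)(p13q22),
t(15;17)(q21;q22), *CEBPA* double mutations and *NPM1* mutations — that
carry distinct miRNA expression programs. `miRsigAML` implements a complete
analysis chain for cohorts of the kind used to establish this:

1. **Normalization** of TaqMan-style Ct values to log2 expression by
   per-sample median centering (`normalizeCt`): one Ct cycle is one
   doubling, undetected reactions enter at the cycle ceiling (Ct 40).
2. **Variance filtering** (`filterVariableMirnas`): a miRNA is kept when at
   least one sample deviates from the cohort geometric mean by at least a
   6-fold factor, i.e. `max_s |x_fs - mean_s(x_f.)| >= log2(6)` on the
   log2 scale (the per-feature mean of log2 values *is* the log2 geometric
   mean of the linear abundances).
3. **Unsupervised clustering** (`pearsonDistance`, `wardCluster`): samples
   are compared by Pearson correlation of their filtered profiles,
   `d = 1 - r`, and agglomerated under Ward's minimum-variance criterion;
   flat clusters are examined for subtype enrichment with one-sided
   hypergeometric tests and for covariate shifts with rank-sum tests,
   Benjamini–Hochberg adjusted per label family (`clusterEnrichment`).
4. **Signature discovery** (`dlcv`): per subtype, a one-vs-rest linear SVM
   inside a double-loop (nested) cross-validation. The inner loop selects
   the signature *size*; the outer loop estimates unbiased performance;
   repeated reshuffles yield per-miRNA selection frequencies from which a
   consolidated signature is read off.
5. **Cross-platform validation** (`crossPlatformValidate`): signatures are
   intersected with the probe content of an independent cohort's platform,
   both cohorts are standardized per feature within themselves, a model is
   trained on the full training cohort and scored on every test sample.
6. **Target analysis** (`consensusTargets`, `inverseCorrelation`): a gene
   is called a target of a miRNA when at least 3 of 5 prediction databases
   agree; called pairs are screened for the expected negative
   miRNA–target correlation (Spearman) on paired expression data.

## The double-loop cross-validation in detail

For subtype *g* with label vector `y` (in-group vs all others):

* Each **run** draws a fresh stratified partition into 3 outer folds
  (100 runs by default; the run count is the resampling depth, not a model
  parameter).
* On each outer-training set, the **inner loop** builds 5 stratified folds
  and, for every candidate size *m* in the grid
  {1, 2, 3, 5, 8, 12, 18, 27, 40, 60}: ranks features by absolute Welch
  *t* statistic on the inner-training split, trains on the top *m*, and
  scores balanced accuracy on the inner-test split. The smallest *m*
  maximizing the mean balanced accuracy wins (parsimony tie-break).
* Features are re-ranked on the whole outer-training set, the top-*m**
  model is trained (features standardized to training mean/variance,
  class-balanced weights `w_c = n / (2 n_c)`, linear kernel, cost fixed at
  1) and scored on the held-out fold. Confusion counts pool per run;
  sensitivity, specificity, PPV, NPV and accuracy are computed per run and
  averaged; undefined ratios (zero denominators) stay `NaN` and are
  excluded from the mean rather than silently zeroed.
* A feature's **selection frequency** is the fraction of outer-training
  fits whose final model contained it. The consolidated signature keeps
  features with frequency >= 0.5, sorted by frequency, capped at the
  median *m** (rounded up when the median falls between grid values).
  Directions (up/down) come from the sign of the in-group minus out-group
  mean on the full cohort.

Data flow is strictly training-sided: ranking, size selection,
standardization and fitting never see the held-out fold. `fitFoldModel`
exposes one fold's fit so this can be asserted directly — perturbing
held-out samples leaves the fitted model bit-identical.

Why cost is not tuned: adding a second hyper-parameter would turn the inner
loop into a joint search and change the procedure's identity; the inner
loop is deliberately a pure signature-size optimization. The cost, grid,
fold counts, tie-break and threshold are all `pipelineConfig()` fields, so
alternative reconstructions are one argument away.

## The synthetic cohort generator

`generateCohort` emulates the study geometry: 664 miRNAs x 165 samples
with subtype groups MLL 36, t(8;21) 21, inv(16) 17, t(15;17) 12, CEBPA-dm
11, NPM1 11 and 57 "other"; planted signatures of 37, 14, 17, 14, 18 and 5
miRNAs respectively (disjoint across subtypes by default; an overlap switch
exists because real CBF-leukemia signatures overlap heavily). The model is
additive on the log2 scale:

```
x[f, s] = baseline[f] + (+-effectLog2) * [f in signature(subtype(s))] + noise[f, s]
```

* `effectLog2 = log2(6) = 2.585` by default — the same 6-fold contrast the
  expression filter encodes.
* `baselineSd = 3` log2 units: the between-miRNA abundance spread typical
  of miRNA arrays after median-Ct normalization (detected miRNAs span
  roughly 10–15 cycles).
* `noiseSd = 1` log2 unit of within-group variability per measurement.
* `directionMix = 0.5`: planted signatures are half up-, half
  down-regulated. The real per-subtype up/down ratios (e.g. 14 up / 23
  down for *MLL*) are presets a user can set, not defaults.
* `missingRate = 0` by default. Nonzero rates mark cells undetected
  uniformly at random and impute them at the cohort floor (the minimum
  simulated value), mimicking detection-limit censoring. Because this
  missingness model is abundance-independent, any imputed cell becomes a
  gross low outlier (the floor sits several standard deviations below a
  random feature's baseline), which trivially passes the fold filter and
  distorts sample correlations; real non-detects concentrate in
  low-abundance miRNAs where the floor is near their true level. The
  mechanism is therefore off by default and available as a stress knob.

What the generator does *not* emulate: correlated miRNA co-expression
(clusters of co-transcribed miRNAs), heterogeneous per-feature effect
sizes, sub-structure inside the "other" group, plate/batch layouts, and
abundance-dependent censoring. Passing recovery tests on these cohorts
therefore demonstrates correctness of the machinery under a clean additive
model, not expected performance on real patient data.

`generateSecondPlatform` models an independent platform as a uniform
random probe subset (`floor(keepFraction * n)` features) plus per-feature
additive offsets `N(0, shiftSd^2)` — the two dominant cross-platform
nuisances for single-channel arrays. `generatePairedMrna` couples
synthetic target genes to their miRNA linearly with negative coupling.

## Numerical and design choices

* **Ward convention**: the Lance–Williams recurrence is applied to the
  `1 - r` dissimilarities as given (`ward.D`); `ward.D2` (squared) is a
  flag. Pairing Pearson distance with Ward is only defined up to this
  convention.
* **Filter comparison** is inclusive (`>=`), deterministic, and the
  geometric mean is computed as the arithmetic mean of log2 values
  (mathematically identical, numerically stable).
* **Ranking ties** (including several perfectly separating features with
  infinite *t*) break lexicographically by feature id in C-locale order,
  making every ranking deterministic.
* **Enrichment**: one-sided hypergeometric over-representation per
  cluster x label; a label absent from the cohort scores p = 1.
* **Degenerate folds**: if the minority class cannot populate the
  requested inner folds, the fold count drops with a warning; below two
  possible folds the call errors rather than report meaningless accuracy.
* **Seeds**: every stochastic stage derives its stream from one integer
  (`rngSeed` in `pipelineConfig`/`cohortDesign`); identical inputs
  reproduce byte-identical reports, which the test suite asserts.
* The subtype vocabulary is closed; cytogenetic spellings are mapped by an
  alias table and anything unrecognized becomes `"other"` with a warning
  (e.g. t(7;12), t(8;16) and *NUP98* rearrangements, which show no
  homogeneous expression cluster and are not classified).

## Known behaviors and limitations

Two properties of the procedure deserve emphasis; both are measured by the
package's own test suite and acceptance script rather than asserted from
theory alone.

**Parsimony bounds signature recovery.** The inner loop returns the
smallest size within ties of the best balanced accuracy. When planted
per-feature effects are strong (2.6–3 log2 units against unit noise), a
handful of features already classifies almost perfectly, so *m** settles
around 3–12 regardless of how many informative miRNAs exist. Selection
then spreads across the (equally informative) planted members, and each
one's selection frequency is roughly `E[m*] / |signature|` — far below the
0.5 consolidation threshold for a 37-miRNA signature, while a 5-miRNA
signature is recovered completely. Large discovered signatures on real
cohorts are thus a sign of *weak, heterogeneous* per-feature effects, not
something a strong uniform-effect simulation reproduces. Classification
performance is unaffected (sensitivity and specificity stay above 90% on
strong-signal cohorts); only full-set recovery is.

**Class-balanced weighting prevents majority collapse on null data.** With
no signal, ranking on training folds picks features whose apparent
separation is sampling noise; held-out samples of both classes land on the
same side of the balanced decision boundary in proportions governed by the
selected dimension count. Mean null accuracy therefore sits 10–20
percentage points *below* the majority-class rate instead of collapsing to
it — the deliberate price of class-balanced weights, which are what make
11-sample subtypes learnable at all. Relatedly, a feature whose
whole-cohort association is spuriously strong ranks high in nearly every
resampled training set: selection frequency guards against fold-level
instability, not against cohort-level artifacts, and null cohorts can show
single features with frequency above 0.8.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full 664 x 165 geometry
for filtering, clustering (10 seeds), DLCV (25 runs for performance and
recovery; 10 runs x 10 seeds for null calibration), a doubled 330-sample
cohort split in half for cross-platform validation, and synthetic
five-database fixtures of a few hundred pairs for target consensus. These
sizes were chosen so each property is measured at the study's cohort scale
while a complete run stays in the minutes range on one CPU.
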