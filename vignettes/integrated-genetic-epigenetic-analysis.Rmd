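---
title: "Integrated genetic–epigenetic analysis of a target CpG: models and methods"
author: "epigx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated genetic–epigenetic analysis of a target CpG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigx)
```

## The scientific problem

Methylation at a handful of CpG sites tracks chronic hyperglycemia; the most
robust of these is cg19693031 in the 3'UTR of *TXNIP*, which demethylates as
HbA1c rises. A CpG's methylation is, however, also shaped by nearby and
distant genetic variation (meQTLs) and by genotype-dependent responses to the
exposure itself (GxE), and HbA1c in turn can depend on CpG-by-SNP
interactions (GxMeth). Ignoring this genetic context confounds the CpG's
value as a type 2 diabetes biomarker. `epigx` implements the full analysis
around one focal CpG: cohort QC, stochastic-epimutation filtering,
genome-wide association and interaction scans, step-wise integrated variance
models, and imbalance-aware disease-status classification — together with a
synthetic cohort generator that provides planted ground truth for every
stage.

## Models fitted by the scans

With $\beta_i$ the focal-probe methylation fraction, $E_i$ HbA1c (%),
$G_{ij}$ the additive dosage of SNP $j$, and Age/Sex/BMI covariates, the
per-feature ordinary-least-squares models are:

* EWAS / polymorphic-probe scan: $E \sim \beta_j + \mathrm{Age} +
  \mathrm{Sex} + \mathrm{BMI}$, ranked by the methylation-term p-value,
  Benjamini–Hochberg-corrected within the family.
* meQTL scan: $\beta \sim G_j + \mathrm{Age}$, with SNPs partitioned into
  cis (same chromosome, distance $\le$ 1 Mb — the boundary is inclusive),
  long-range cis (same chromosome beyond 1 Mb) and trans.
* GxE scan: $\beta \sim G_j \times E + G_j + E + \mathrm{Age}$, ranked by
  the interaction-term p-value.
* GxMeth scan: $E \sim \beta \times G_j + G_j + \beta + \mathrm{Age} +
  \mathrm{Sex} + \mathrm{BMI}$, interaction p Bonferroni-corrected at the
  family size, with the SNP additive p reported alongside.

p-values come from classical homoskedastic t statistics — the plain linear
model machinery used in practice for these scans; no robust or sandwich
errors are offered. Each fit uses complete cases for that feature and
records `n_used`. Adjusted $R^2$ is $1-(1-R^2)(n-1)/(n-p-1)$. The scan core
is a per-feature QR decomposition algebraically identical to
`summary(lm())`; oracle-equivalence tests assert agreement with one-at-a-time
`lm()` fits at $10^{-8}$.

## Stochastic epimutations

A probe's stochastic epimutations (SEMs) are values outside Tukey-style
fences widened to three interquartile ranges: above $Q_3 + 3\,\mathrm{IQR}$
a high methylation outlier (HMO), below $Q_1 - 3\,\mathrm{IQR}$ a low
methylation outlier (LMO). Numerical choices, each tested: quartiles by
linear interpolation between order statistics (`quantile` type 7); fences
computed from **all** values of the probe, candidates included; strict
inequalities, so a value exactly on a fence is not called; probes with fewer
than 8 non-missing values are skipped with a warning. Fences are affine
equivariant, so the call set is invariant under affine rescaling of a probe.

Carrier enrichment in diabetic versus non-diabetic subjects uses the
two-tailed Fisher exact test with the exact conditional-MLE odds ratio and
CI, on the fixed orientation rows = (diabetic, non-diabetic) × columns =
(has SEM, no SEM). The subject, not the call, is the independent unit: SEM
calls within a subject are correlated, so an exact test on call counts would
not be valid. In the downstream pipeline SEM-carrying probes are dropped,
with one deliberate exception: the focal probe anchors every SNP scan and is
retained even if it carries calls, because fence-exceeding values at the
target arise from the genuine dose response in the skewed exposure tail, not
from epimutation.

## Step-wise integrated models

Candidates (meQTL main effects; interaction terms written `snp:hba1c`) are
screened by univariate adjusted $R^2$ (defaults 0.03 for meQTL candidates
and 0.1550 for interaction candidates — the screens used in this literature)
and offered in decreasing order. A candidate is retained iff its coefficient
stays significant in the joint fit (default $\alpha = 0.05$) *and* the
extra-sum-of-squares F-test against the model without it is significant
(default $\alpha = 0.05$). After each accepted addition all previously
retained candidates are re-tested once and non-significant ones dropped — a
single sweep, chosen because the procedure described in this literature
drops destabilised terms but never states a schedule. Interaction
candidates always bring both parents into the model and parents of a
retained interaction are never swept out (model hierarchy). Candidates that
are collinear with the current model (condition number above $10^8$, or
aliased) are skipped with a history entry. The G+E model in the pipeline is
the final genetic model plus the exposure, so the genetic/G+E comparison is
an honest nested F-test.

Genotype-stratified comparisons of focal-probe methylation use Welch's t
pairwise between dosage groups (groups below 3 subjects are reported
untested), Holm-corrected within each stratum's pairwise family. The effect
size is the pooled-SD standardized mean difference with a seeded bootstrap
percentile 95 % CI (2,000 resamples); the estimator behind published effect
sizes of this kind is not stated, so no numerical match to any published
value is attempted.

## Classification

The three-way glycemic status is analysed as binary contrasts (the
control-versus-diabetic contrast drives the integrated classifier). The
logistic baseline uses a stratified 70/30 train/test split. The balanced
random forest (BRF) draws, for every tree, a bootstrap with equal numbers
from both classes — the majority class randomly under-sampled — which the
package realises through class-wise sampling fractions in `ranger`; an
instrumentation hook (`brf_inbag_class_counts`) exposes the per-tree in-bag
class counts so the contract is testable. Evaluation is repeated stratified
cross-validation (defaults 10 splits × 3 repeats); fold assignment is a
deterministic seeded round-robin within class, keeping every fold's class
ratio within one subject of the global ratio. Aggregate metrics are the
mean of per-fold AUC/sensitivity/specificity/precision (pooled-prediction
aggregation is available via `aggregate = "pooled"`); the confusion matrix
is always pooled. AUC uses the rank (Mann–Whitney) formulation with
mid-rank tie correction; threshold metrics use 0.5 by default. Forest
hyperparameters (500 trees, $\sqrt{p}$ features per split, unlimited depth)
are conventional defaults, configurable in `cv_config()`.

Feature selection follows the published ordering: one balanced forest on all
data, keep features with Gini importance above the mean (plus always-keep
columns: covariates and the target CpG), then rank by importance averaged
over the CV repeats and keep the top 13 (ties broken lexicographically for
determinism). Selecting on the full data before cross-validated evaluation
risks selection leakage; the package keeps the published ordering as the
pipeline default and the criterion that matters for honesty here — planted
discriminative features versus a covariate-only baseline, and chance-level
AUC under label permutation — is tested on both paths. A fully nested
selection can be composed from the exported building blocks by running
`implicit_feature_select()` inside each training fold.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes; its
defaults describe a realistic mid-life, predominantly female cohort with an
imbalanced glycemic spectrum.

* **Glycemic strata.** Class proportions 142/274/90 (control, prediabetic,
  diabetic) out of 506; HbA1c drawn from truncated normals within each
  clinical bin with the published group means and SDs (5.34 ± 0.26,
  5.96 ± 0.21, 8.02 ± 1.84), giving the right-skewed mixture. Age is drawn
  per class (45.3/46.7/52.1, SD 8.4/7.3/9.7), sex is 75 % female, BMI is
  log-normal matched to the group means, and self-report diagnosis/treatment
  flags use the published per-class rates, so the exclusion rules have work
  to do.
* **Genotypes.** MAF uniform on (0.05, 0.5] by default, dosages binomial(2,
  MAF) (Hardy–Weinberg), features scattered uniformly over 22 chromosomes;
  optional missingness never touches planted SNPs. No linkage structure is
  simulated — LD pruning is tested separately on duplicated columns.
* **Focal probe.** A unit-variance latent score combines centred exposure,
  age, planted SNP main effects and SNP×exposure products plus Gaussian
  noise, then maps through a logistic link centred at 66 % methylation with
  scale 0.4 — small enough that the link is near-linear over the realised
  range, so latent variance fractions approximate observed $R^2$. Scaling
  is exact in sample: planted columns are standardised by their sample
  spread and the noise is residualised against the planted design, so each
  term's realised latent fraction equals its configured value in every
  dataset rather than only in expectation. The exposure coefficient is
  negative (demethylation with rising HbA1c).
* **GxMeth.** Planted CpG-by-SNP terms perturb HbA1c on the exposure scale
  after the probe is built, and the glycemic class is re-binned. The
  pipeline default effect (8 % HbA1c per unit of centred dosage × centred
  beta) yields an interaction partial $R^2$ near 0.05 — deliberately
  conservative relative to the top published GxMeth associations, whose
  p-values at n ≈ 500 imply partial $R^2$ near 0.14.
* **SEM probes.** Background probes are null logit-normal noise
  (beta-scale means uniform on (0.15, 0.85), logit SD 0.2–0.3). Probes named
  in `planted_sem` use a tighter spread and have the requested number of
  values placed strictly outside the 3×IQR fences of the remaining subjects,
  clipped inside (0, 1).
* **Determinism.** One integer seed drives every draw; identical configs
  produce byte-identical matrices.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic LD and population structure, cell-type
composition, array chemistry and normalisation artifacts, batch effects,
and missingness mechanisms beyond missing-completely-at-random.

## Known statistical properties and limitations

Because the exposure is a skewed mixture, classical interaction t-tests in
the GxMeth scan are anticonservative under the *default* (non-null) cohort
(genomic inflation λ ≈ 1.8 in our checks) — a real property of plain linear
models under heteroskedasticity that practitioners of these scans will
recognise. Under the global null (no planted effects, exposure and age
fractions zero) all scans are well calibrated and both BH-FDR and
Bonferroni control their nominal rates in Monte-Carlo checks. Detection
power for a planted meQTL of latent fraction 0.04 at n = 500 sits near the
theoretical boundary for a $p < 10^{-3}$ threshold; the exact in-sample
scaling above is what makes the recovery rate stable.

## Problem sizes used in the shipped checks

The package's test suite and `scripts/acceptance.R` exercise: oracle
equivalence on 100 probes + 100 SNPs at n = 500; null calibration on 40–60
seeded cohorts of 1,000 probes / 2,000 SNPs at n = 500; SEM agreement with a
brute-force oracle on 1,000 random probes plus 800 clean probes for the
false-call rate; planted-effect recovery over 60–100 seeds of 1,000-SNP
cohorts; stepwise recovery over 60–100 seeds of 20 candidates at n = 500;
and classifier comparisons over 20–25 seeds of ~400-subject cohorts with
5 × 2 cross-validation and 150–200 trees. These sizes are the package's
choice of simulation scale; all thresholds are stated in the tests
themselves.

## A short worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  seed = 5,
  sim = list(n_subjects = 250, n_probes = 120, n_snps = 400,
             planted_meqtl = list(list(snp_id = "snp_00042", fraction = 0.05)),
             planted_gxe = list(list(snp_id = "snp_00123", fraction = 0.05)),
             planted_gxmeth = list(list(snp_id = "snp_00300", effect = 8)),
             planted_sem = list(list(probe_id = "cg_00007", n = 3,
                                     direction = "high"))),
  cv_splits = 5, cv_repeats = 2, num_trees = 100)
res <- run_pipeline(cfg, "epigx_out")
glance(res$models$integrated)
glance(res$classify$reports$pruned)
autoplot(res$scans$gxmeth)
```
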