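---
title: "Multi-omic analysis of growth-cone development and optic-nerve regeneration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic analysis of growth-cone development and optic-nerve regeneration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmultiomics)
```

# The scientific problem

Growth cones — the motile tips of growing axons — drive neurite elongation
through continuous expansion of their plasma membrane, a process governed by
protein–lipid interactions. This package implements a reusable pipeline for
two linked analyses:

1. **Development arm.** Joint proteomic and lipidomic profiling of growth
   cones across five developmental stages (E18, P0, P3, P6, P9) and two
   subcellular fractions (growth cone membrane, GCM; growth cone
   particulate, GCP), asking which proteins and lipid classes track
   developmental stage, how fraction and age partition the molecular
   variance, and which protein–protein interactions co-trend with the lipid
   classes they may regulate.
2. **Regeneration arm.** Lipidomics of adult optic nerve after crush
   injury, with regeneration induced by intravitreal Wnt3a or Zymosan,
   asking which lipid species and biophysical lipid properties mark the
   transition into a growth-permissive state, and how that signature
   overlaps the early-development growth-cone signature.

Because raw LC–MS/MS data are not redistributable at desk scale, the
package ships a synthetic-data module that generates datasets with the same
design and with *planted, recorded* effects, so that every downstream stage
can be exercised and validated by parameter recovery.

# The synthetic-data model

## Noise

Measurement noise is multiplicative lognormal. A target coefficient of
variation `CV` maps onto a log2-space standard deviation

$$\sigma_{\log_2} = \sqrt{\ln(1 + CV^2)} / \ln 2,$$

which makes the realized CV of replicate raw intensities equal to the
target exactly (in expectation). The default `noise_cv = 0.08` reflects the
replicate reproducibility reported for fractionated growth-cone
preparations (median within-stage CVs under 11% for the proteome and under
10% for the lipidome); with six replicates per stage-by-fraction cell the
realized median CV of a simulated dataset falls in roughly 7–8%, and a
seeded calibration test asserts the [0.06, 0.10] band. Baseline abundances
are lognormal (`log2` mean 20, SD 2), a standard approximation for MS
intensity distributions; no public raw-intensity distribution was available
to fit, so this is an explicit model assumption recorded in the generator
configuration.

## Planted effects (all additive in log2 space)

* **Protein stage trends** — 60 + 60 proteins with linear per-stage slopes
  of ±1.5 noise-SD (≈ ±0.17 log2 per stage, a ~1.6-fold span from E18 to
  P9). Linear trends are what the analysis's Pearson trend filter assumes.
* **Fraction effect** — 150 proteins shifted +1.5 log2 (≈2.8-fold) in GCM.
  The shift must clear the volcano's fold-change gate (2.0) to be
  recoverable; it also makes the fraction the dominant variance axis,
  which is how such fractionation designs behave in practice.
* **Lipid-class switching** — species of the early classes (TG, DG, MG,
  ChE, ZyE, So) follow an early/late step contrast (elevated at E18/P0,
  depressed at P3–P9) with amplitude 4 noise-SD; late classes (CerG1, LPC,
  LPS, LPG) follow its negative. A *step* rather than a pure linear ramp is
  used deliberately: class switching is the planted structure the two-means
  early/late split must recover, and with five equally spaced stages a
  linear ramp makes the k = 2 partition of {E18,P0} versus {P3,P6,P9}
  degenerate (the {E18,P0,P3} cut has identical within-cluster variance).
  The step contrast still has |Pearson r| ≈ 0.87 against the stage
  ordinal, so class–stage trend calls keep the expected signs.
* **Protein–lipid coupling** — for four classes (TG, ChE, CerG1, LPC),
  four proteins each share the class's stage profile (amplitude 4
  noise-SD). These proteins genuinely trend, so they are included in the
  planted trend sets; they seed the planted protein–protein edges and the
  two planted complexes (the 8 positively co-trending proteins, and a
  dimer from the negatively co-trending ones).
* **Regeneration arm** — group sizes 21 control / 16 crush+saline / 6
  Wnt3a / 10 Zymosan across days 3, 7 and 15; one marker species,
  `Cer(d18:1/24:0)`, elevated by 8 noise-SD in every regenerating sample
  (complete separation); nine species (eight PC, one PE) depleted −2 log2
  in the crush+saline arm only — the saline arm carries the injury
  signature while the induced-regeneration arms model recovered membranes,
  which keeps the crush volcano and the ROC ranking independently
  recoverable; class-level shifts for regenerating samples (day 7: TG +0.6,
  CerG1 −0.6; day 15: TG +1.8, MG +1.5, PG +1.5, CerG1 −1.8 log2). Day-3
  regenerating samples carry no class shift, so class-shifted species
  plateau near AUC 0.88 and cannot tie the marker.
* **Batch structure** — two acquisition batches (Wnt3a arm with half the
  controls/crush samples; Zymosan arm with the rest). Batch effects are
  per-feature offsets drawn around the batch's nominal shift (0.8 vs 0
  log2, feature SD 0.15). They are feature-specific on purpose: a shift
  uniform over features is a whole-sample scale factor that column
  normalization removes exactly, leaving nothing for batch correction to
  do. The 0.15 log2 feature SD (~11% per-feature bias) matches within-lab
  LC–MS batch reproducibility and keeps the planted 8-SD marker separation
  recoverable after empirical-Bayes correction.

Species names are drawn from a shorthand grammar
(`CLASS(chain/chain...)`, chains `carbons:double_bonds` with optional
`d`/`t` sphingoid prefixes), with double-bond counts spanning 0–6 so the
unsaturation-based ontology terms are populated. Class membership is
uniform over a 20-class pool, topped up so no effect-carrying class is
empty by chance.

## What the generator does *not* emulate

No spectra, retention times, identification error, adducts, isotopes,
missing values, or intensity drift. Passing recovery tests therefore shows
that the *statistical pipeline* behaves as specified on data with the
assumed structure — not that the pipeline is robust to identification or
acquisition artifacts in real LC–MS data.

# Analysis methods

## Normalization and QC

Default normalization is total-intensity scaling (columns scaled to the
mean column sum) followed by `log2(x + 1)`; MS normalization conventions
vary, so the choice is recorded in the run configuration and report.
The regeneration pipeline uses **median** normalization instead: induced
regeneration moves whole lipid classes several-fold, which violates the
constant-column-sum assumption behind total-intensity scaling (the inflated
TG/MG/PG totals would drag every other species down in regenerating
samples), while the column median is robust to a minority of strongly
shifted species. Coefficients of variation use the n−1 SD on raw
intensities within stage-by-fraction cells; because reported CVs can be
computed on raw or normalized intensities, the report carries both the
within-group and the pooled across-group dispersion.

## Multivariate analysis

* **PCA** is SVD-based on feature-centered data with a deterministic sign
  convention (largest-magnitude loading positive per component).
* **ASCA** partitions the feature-centered matrix into per-factor effect
  matrices (level-mean deviations), an interaction matrix (cell means minus
  main effects) and a residual, then runs PCA per effect matrix. The
  residual is defined as the remainder, so the decomposition identity holds
  on any design; sums of squares are additive and effects pairwise
  orthogonal on balanced designs (tested at 1e-9). For a two-level factor
  the effect matrix has rank one, hence "the fraction effect's PC1 carries
  100% of its variation" is structural — the informative quantity is the
  effect's share of total sum of squares, which is also reported. Both
  readings of "percent of variation explained" are defensible; this
  package reports effect-matrix PCA ratios for the PC1 statement and SS
  shares alongside.
* **PLS stage regression** is single-response NIPALS with deflation on
  autoscaled features against the centered stage ordinal (E18 = 0 … P9 =
  4, equally spaced — the encoding is a package choice). VIP scores use
  the standard weight/SSY formula and satisfy ΣVIP² = p exactly. Q² uses
  7-fold cross-validation stratified by stage with in-fold re-scaling
  (PRESS/TSS against the training mean). "Accuracy" is interpreted as the
  fraction of samples whose continuous prediction rounds (clamped to the
  ordinal range) to the true stage — a deliberate interpretation of
  "accuracy" for an ordinal response, recorded here. The in-package
  NIPALS is cross-checked against an independent PLS implementation to
  1e-10 on fitted values and VIP.
* **Ward clustering** uses `hclust(method = "ward.D2")` on Euclidean
  distances between autoscaled samples; purity is the percentage of
  samples in clusters whose majority label matches their own.
* **k-means early/late split** runs `stats::kmeans` with 50 random
  restarts under a fixed seed (Hartigan–Wong; restarts serve the same
  robustness purpose as k-means++ seeding) and labels the cluster with the
  lower mean stage ordinal "early".

## Differential and trend statistics

Welch (unequal-variance) t-tests throughout — Welch is the safer default
when replicate variances cannot be assumed equal. log2 fold change is the
difference of group means in log2 space. Benjamini–Hochberg correction is
applied within each analysis family (per fraction, per contrast), not
globally. Stage trends are Pearson correlations against the ordinal with
two-sided p from the t distribution (n−2 df); the default gates are
`p < 0.01` and `|r| > 0.7`, applied on raw p (q is also reported). Zero-variance features are
excluded with a reason rather than tested.

## Enrichment

Term enrichment is the one-sided upper-tail hypergeometric (Fisher exact)
test against the detected-feature background with BH correction; the
depletion tail is reported alongside. The background is the set of detected
features in the relevant fraction — detection-conditioned enrichment is
standard. The lipid ontology is
replaced by a packaged static class-to-term table (storage/membrane roles,
headgroup charge, lateral diffusion, bilayer thickness, intrinsic
curvature, transition temperature) plus unsaturation terms computed from
parsed chain composition; it is a labeled stand-in, not a reconstruction of
any external database's statistic.

## Protein–lipid network

Protein–lipid correlations are Pearson over the intersection of sample ids
(the two omics layers need not share all samples). Protein–protein edges
from a STRING-like table are retained only if (1) both endpoints are in the
detected proteome and (2) the endpoints' abundance profiles correlate
significantly with each other (Pearson p < 0.01 across the fraction's
samples, either sign) — the dual requirement. Correlations are combined by
Fisher's r-to-Z-to-r (mean on the atanh scale, back-transformed), with
inputs clipped at ±(1 − 1e-6) to keep the transform finite. Per-protein
class-level correlations combine over species within each class; combining
over classes instead is a noted alternative. Complexes are summarized by
the Fisher-combined member stage correlations; complexes with fewer than
two detected members are flagged, not dropped.

## Batch correction and ROC ranking

Batch correction is parametric empirical-Bayes location/scale adjustment:
features standardized against the batch-size-weighted grand mean and pooled
variance; per-batch per-feature means and variances shrunk toward
normal/inverse-gamma priors with method-of-moments hyperparameters by
iterated posterior updates (tolerance 1e-4, max 100 iterations). Two
deliberate boundary choices: with a single batch the adjustment is the
identity (the across-batch hyperpriors are undefined, and there is nothing
to correct), and after adjustment each feature is re-centered to its
pre-adjustment grand mean (a location-only recentring that leaves batch-gap
removal untouched but makes "correction never moves a feature's average"
an exact invariant). The implementation is cross-checked against the
reference EB implementation on simulated data.

ROC ranking uses the midrank Mann–Whitney AUC (ties get half credit),
orientation-corrected to ≥ 0.5 with the direction recorded, verified
against brute-force pair counting for all small group sizes. The reported
accuracy is taken at the Youden-optimal threshold. Wnt3a and Zymosan
samples are pooled as "regeneration" across days (16 vs 21 controls) for
the combined comparison; a per-day restriction is available by subsetting
the metadata.

# Numerical and degenerate-input choices

* Tolerances: ASCA identity/orthogonality 1e-9 (relative); VIP
  normalization 1e-9; AUC/hypergeometric oracle agreement 1e-12;
  single-batch identity 1e-8; autoscaling 1e-12 (mean) and 1e-9
  (variance).
* Zero-variance features: error in PCA/autoscaling (with advice to
  remove), exclusion-with-reason in trend tests, NA-with-flag in
  correlation matrices.
* Degenerate t-tests (zero variance in both groups) return p = 1 when the
  means agree and p = 0 when they differ.
* k-means on identical points returns a single cluster with a warning.
* Ties in the ROC ranking are broken by feature id for determinism.

# Problem sizes and runtime

The packaged study conditions (600 proteins, 200 lipid species, 58 + 53
samples) run each full pipeline in under a second, so the test suite can
afford seed sweeps: 50-seed recovery loops for clustering and marker
ranking, 100-seed null-calibration loops for type-I error, and a 200-seed
Monte-Carlo check that a zero-separation marker has chance-level AUC. The
whole suite completes in well under a minute on one CPU.

# Known limitations

* The generator's effects are clean (additive in log2, no missingness, no
  outliers); recovery rates here are upper bounds on real-data behavior.
* The ontology stand-in encodes class-level membership only; term
  enrichment on real data would use a curated lipid ontology with
  species-level annotations.
* ComBat-style correction assumes the batch/treatment confounding is
  partial; with fully confounded designs (every treatment in exactly one
  batch and no shared controls) location/scale adjustment would absorb
  treatment signal, and no covariate-preserving variant is provided.
* The PLS "accuracy" definition is an interpretation (rounded ordinal
  match); other conventions (e.g. class-wise discriminant accuracy) would
  give different numbers.
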