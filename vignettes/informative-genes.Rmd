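---
title: "Modeling drug response with informative gene subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug response with informative gene subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inforx)
library(dplyr)
```

## The problem

Pharmacogenomic screens expose panels of cancer cell lines to anti-cancer
compounds and record, per cell line and drug, the ln IC50 — the natural log
of the concentration that halves viability. Basal gene expression is the
single most predictive data layer for this response, but the transcriptome
is wide (tens of thousands of genes for under a thousand cell lines) and
most genes are irrelevant to any particular drug. `inforx` implements two
complementary ways of picking informative feature genes before fitting a
regression of ln IC50 on expression, together with the permutation
protocols, baselines and downstream analyses needed to judge them.

Expression enters the pipeline z-scored **within each cell line** across
genes (the panel-wide preprocessing convention; `zscore_cell_lines()`).
A second, separate standardization — per gene, with training-block
statistics only (`standardize_genes()`) — is applied inside every model
fit, so no held-out cell ever informs a scale.

## The two selection procedures

**Drug-unspecific genes (DUG).** Genes are ranked by the sample variance of
their expression over the training cells (`rank_by_variance()`); the top
*n* (default 5000; size grid 25/100/1000/5000/10000 available in
`pipeline_config()`) are kept, and redundancy is removed by clustering:
any two candidates whose expression profiles correlate at |r| ≥ 0.8 are
linked, and each connected component keeps its highest-variance member
(`select_dug()`). The clustering rule itself is not fully dictated by the
procedure's description; single-linkage components with a
highest-variance representative were chosen because the result is
parameter-free and independent of gene order. Absolute correlation is used
for redundancy edges (anti-correlated duplicates carry the same linear
information); a `signed` flag flips this. One DUG set serves every drug.

**Drug-specific genes (DSG).** Per drug and per training split, the cells
are sorted by each gene's expression; the top and bottom 10% (tail size
`max(2, floor(0.1 n))` — the floor keeps the correlation defined, since the
source procedure states "10%" with no rounding rule) are retained and the
gene's expression is correlated with ln IC50 **on those extreme cells
only**. Genes reaching |r| ≥ 0.4 — inclusive, following the procedure's
"equal or higher" wording — are the drug's informative set
(`select_dsg()`). Cells with a missing response for the drug are removed
before the tails are formed; expression ties are broken by cell-line id so
the subset is deterministic across platforms.

## Protocols and learners

Two split protocols, both driven by seeds derived from
`(master_seed, drug, protocol, permutation)` so that different methods can
be compared on *identical* splits:

* **Elastic net (ENR), 80/10/10.** Per permutation: shuffle, cut into
  train/test/validation; screen DSG on the training block only; fit
  `glmnet` with the mixing parameter on the grid 0.1–1.0 (step 0.1) and the
  penalty on glmnet's log-spaced path, both chosen once per permutation on
  the validation block. The 80/10/10 partition is fixed by the protocol;
  the specific grid is this package's choice.
* **Gaussian-kernel SVR (and random forest), 90/10 with inner 5-fold CV.**
  Ten random splits per drug; cost {0.1, 1, 10}, kernel width at the
  median-heuristic bandwidth × {0.5, 1, 2} and epsilon {0.01, 0.1} tuned by
  5-fold cross-validation inside the training block. The Gram matrix is
  precomputed per split from the pairwise squared distances and
  re-exponentiated per candidate bandwidth, which keeps the 18-point grid
  affordable. The forest (500 trees, mtry = ⌈√p⌉) is included for the
  three-learner comparison and is not tuned further.

Performance per permutation is the Pearson correlation between predicted
and observed ln IC50 on the test block (`r_pred_obs`) plus the mean
absolute error; `glance()` averages the non-degenerate permutations per
drug and reports a Monte-Carlo standard error so reduced permutation
counts are visible. Default `n_permutations` is 100 (full-scale screens
use 10000); the examples and tests in this package run 5–20.

Numerical edge cases are resolved totally rather than propagated: a
constant *observed* test vector flags the permutation degenerate and drops
it from summaries; a constant *prediction* vector (a null model that kept
no feature) scores `r_pred_obs = 0` — no predictive information — rather
than `NaN`; genes constant in a training block are dropped from the fit
with a warning; a drug whose every permutation yields an empty DSG screen
is reported as having no drug-specific genes instead of silently being
modeled on all genes. Single-feature sets are padded with an inert zero
column so the penalized fit remains well-defined.

## Target-context gene sets

For drugs with annotated protein targets, `neighborhood_set()` expands a
breadth-first frontier from all targets jointly over interaction edges with
score **strictly** above 0.9 (the floor follows the "higher than"
convention verbatim), to depth 1/2/3 (P1/P2/P3); `pathway_sets()` collects
the pathways containing a target one by one (F1) or merged (F2);
`random_control_set()` draws size-matched uniform controls. Targets are
included in their own sets — whether the original construction kept them is
not documented, but excluding the one gene known to matter would be hard to
defend; `include_targets = FALSE` flips this.

## Downstream analyses

* `binarize_by_median()`: responses strictly above the drug's median are
  "resistant", everything else "sensitive" (ties go to sensitive — "higher
  than the median" defines resistance, so the rule stays total).
  `classification_metrics()` uses sensitive as the positive class and
  defines any zero-denominator metric as 0 (the common MCC convention).
* `drug_unique_genes()`: per gene, DSG selection counts are z-scored
  across drugs (sample sd; the z is across drugs per gene, which is what
  "its z-score" for a gene can sensibly mean) and the gene is unique to
  the top drug iff z_top ≥ 3 > z_second. Note an arithmetic consequence:
  a lone spike among m drugs has z = (m−1)/√m, so with fewer than 11
  drugs the rule can never fire.
* `gene_contribution()`: leave-one-gene-out over identical split plans, so
  the performance drop is attributable to the removed gene.
* `fingerprint_similarity()` (Tanimoto/Tversky on bitsets) and
  `ic50_profile_similarity()` (complete-observation Pearson of two drugs'
  response profiles).
* `class_loo_predict()`: predicts a held-out drug from its classmates'
  DSG sets. The averaging target is genuinely ambiguous; both readings are
  implemented, and neither is asserted as the original. The default,
  `label_transfer`, trains each classmate's model on the classmate's own
  response and never touches the held-out drug's labels — matching the
  motivating scenario of a novel, unscreened drug; `feature_transfer`
  trains on the held-out drug's labels with each classmate's genes.
* `mutation_association()`: Mann-Whitney comparison of ln IC50 between
  mutated and wild-type cells per gene (≥3 per group), BH-adjusted across
  the tested family. "Adjusted p" names no procedure in the source;
  Benjamini-Hochberg is the field default for screens of this kind, with
  the family being all genes tested for the drug. All tests are two-sided.

## The synthetic cohort generator

`generate_cohort()` draws latent expression i.i.d. N(0,1) per (cell,
gene), plants per-drug causal sets of size k (with a shared core within
each drug class controlled by `class_overlap`), generates
ln IC50 = Σ w_j x_j + ε with ε ~ N(0, noise_sd²), applies a Bernoulli
missing mask, and only then z-scores expression within cell lines — the
response depends on *raw* expression, mimicking a pipeline in which
normalization is a preprocessing artifact. Exact duplicate genes can be
appended for redundancy tests; `generate_context_fixtures()` derives a
target-centered interaction network (scores straddling the 0.9 floor),
pathways holding a configurable fraction of each causal set, and
class-structured fingerprints. Every draw derives from one master seed via
counter-based child seeds, so adding drugs never shifts earlier draws.

Defaults (200 cell lines, 1000 genes, 6 drugs in 2 classes, k = 10 causal
genes, unit weights, noise_sd = 1, 5% missing responses) put each causal
gene at a population correlation of 1/√(k + noise_sd²) ≈ 0.30 with the
response and give tails strong enough for the extreme-decile screen to
recover most of the causal set — a regime comparable to the moderate
effect sizes seen in real panels.

Two analytic facts about this generator shape what tests against it can
show. First, with k independent causal genes the squared per-gene
correlations sum to the signal's variance fraction, so no calibration can
push every per-gene |ρ| above 1/√k; `calibrate_noise_sd()` solves the
population equation for an attainable target and warns (returning a
near-noiseless floor) for an unattainable one. Second, the extreme-decile
subset inflates a gene's spread by a factor s ≈ 1.80 (10% + 10% normal
tails), so the screened correlation is bounded by s/√(s² + k − 1):
screening at |r| ≥ 0.4 can fully recover dense causal sets only up to
roughly k ≈ 10. Larger planted sets are intrinsically under-selected —
a property of the linear-Gaussian design, not of the implementation — and
in that regime a whole-genome elastic net, which sees every causal gene,
is the stronger model. The planted-recovery tests therefore demonstrate
correct mechanics and calibrated behavior in the feasible regime, not
superiority of the screen for arbitrarily dense signals.

What the generator does **not** emulate: microarray noise structure,
tissue-of-origin covariates and batch effects, correlated co-expression
modules (beyond explicit duplicates), non-linear or interaction effects in
the response, and informative missingness. Results on it validate
machinery and statistical calibration, not biological performance claims.

## Problem sizes used by the test suite

The package's checks run, by choice, at desk scale: oracle equivalences on
hundreds of random micro-fixtures; planted-recovery and null-control
cohorts of 300 cells × 2000 genes × 6 drugs with 20 permutations;
contribution and class-transfer studies at 100–150 cells with 5–10
permutations over 20 seeds. The full-scale protocol (10⁴ permutations,
~10³ cell lines, ~1.7 × 10⁴ genes) is a configuration change
(`pipeline_config(n_permutations = 10000)`), not a code change.

## Known limitations

* The elastic-net tuning uses the validation block once per permutation
  (not repeatedly), the straightforward reading of the 80/10/10 protocol.
* The redundancy clustering of the DUG stage is quadratic in `top_n`
  (a 5000-gene correlation matrix is the practical ceiling).
* `run_all()` orchestrates simulate → select → model → compare from one
  configuration and writes TSV/JSON artifacts plus a manifest; it does not
  integrate with workflow engines.
* Raw microarray preprocessing, database retrieval (interactions,
  pathways, compound structures) and GO enrichment are out of scope; the
  package consumes their standard file formats (TSV matrices, GMT,
  edge lists, fingerprint bitsets) instead.
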