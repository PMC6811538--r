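# inforx

Informative-gene selection and drug-response modeling for pharmacogenomic
screens.

Large cell-line panels measure, for hundreds of anti-cancer compounds, the
ln IC50 — the log concentration halving viability — alongside basal gene
expression. Expression is the most predictive layer for this response, but
the transcriptome is far wider than any drug's actual response machinery,
and models fit on all genes are noisy and hard to interpret. `inforx` is
for computational pharmacologists who want to *select* the genes that
carry a drug's response signal and quantify what that selection buys:

* **DUG (drug-unspecific genes)** — one set for all drugs: genes ranked by
  expression variance across training cell lines, top *n* kept, redundancy
  removed by clustering profiles with |r| ≥ 0.8 and keeping each cluster's
  highest-variance member.
* **DSG (drug-specific genes)** — per drug and per training split: cells
  are sorted by each gene's expression, the top and bottom 10% retained,
  and the gene is selected when its expression correlates with ln IC50 at
  |r| ≥ 0.4 on those extreme cells only.

Selected genes feed regressions of ln IC50 on expression —
elastic net (glmnet; mixing and penalty tuned on a validation block under
an 80/10/10 permutation protocol), Gaussian-kernel SVR (kernlab; cost,
bandwidth and epsilon tuned by inner 5-fold CV under a 90/10 protocol) and
random forest — scored by R_pred-obs, the Pearson correlation between
predicted and observed ln IC50 on held-out cells, and by MAE. Around the
core sit the analyses that make the results interpretable: interactome
neighborhoods (P1/P2/P3) and pathway sets (F1/F2) of annotated drug
targets with random size-matched controls, per-drug method comparisons
(Welch t, BH-adjusted), median-split response binarization with
precision/recall/specificity/MCC, drug-unique genes (selection-frequency
z ≥ 3 for exactly one top drug), leave-one-gene-out contribution,
fingerprint (Tanimoto/Tversky) and IC50-profile drug similarity,
drug-class leave-one-out transfer, and mutation–response association
(Mann-Whitney, BH).

Because real screening panels are external downloads, the package ships a
synthetic-cohort generator with planted ground truth
(`generate_cohort()`): linear-Gaussian responses on i.i.d. expression,
class-structured causal sets, missing-response masks, duplicate genes,
and matching network/pathway/fingerprint fixtures — every stage of the
pipeline is testable end to end, with known answers, offline.

## Worked example

```r
library(inforx)

cohort <- generate_cohort(simulation_config(seed = 42))
cohort
#> <inforx synthetic cohort> 200 cell lines x 1000 genes, 6 drugs (2 classes)
#>   10 causal genes/drug, noise sd 1, 5% responses missing, seed 42

# screen drug-specific genes for one drug on the full panel
screen <- select_dsg(cohort$expression, cohort$response, "drug_01")
sum(screen$selected)
#> [1] 21
head(dplyr::arrange(screen[screen$selected, ], dplyr::desc(abs(r))), 3)
#>   gene_id     r selected
#> 1 g0415   0.626 TRUE
#> 2 g0476   0.597 TRUE
#> 3 g0613   0.592 TRUE
```

All three top hits are planted causal genes of `drug_01`. The full
pipeline re-screens inside every training split (no leakage), fits the
elastic net and averages over permutations:

```r
cfg <- pipeline_config(n_permutations = 10, master_seed = 42)
dsg <- run_dsg_pipeline(cohort$expression, cohort$response,
                        c("drug_01", "drug_02"), cfg)
glance(dsg)
#>   method  drug_id n_permutations mean_r  sd_r mc_se_r mean_mae mean_n_features
#> 1 dsg_enr drug_01             10  0.647 0.116  0.0368     2.10            31.3
#> 2 dsg_enr drug_02             10  0.826 0.104  0.0329     1.42            37
```

`mean_r` is the average R_pred-obs across permutations: ~30 selected genes
predict held-out response at r ≈ 0.65–0.83 here, against a planted
per-gene signal of ρ ≈ 0.30. Selection frequencies (`dsg$selection_counts`)
show which genes drive this — stably selected genes are the substrate of
the drug-unique-gene rule (`drug_unique_genes()`):

```r
dplyr::slice_max(dplyr::filter(dsg$selection_counts, drug_id == "drug_01"),
                 count, n = 5)
#>   drug_id gene_id count n_permutations
#> 1 drug_01 g0148      10             10
#> 2 drug_01 g0370      10             10
#> 3 drug_01 g0415      10             10
#> 4 drug_01 g0476      10             10
#> 5 drug_01 g0613      10             10
```

`tidy()` returns per-permutation outcomes, `autoplot()` draws the
per-drug performance distributions, and `run_all(config, out_dir)` drives
the whole flow (simulate or load → context sets → DUG/DSG → models →
comparisons → reports) from one configuration list or YAML file, writing
TSV/JSON results plus a reproducibility manifest.

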