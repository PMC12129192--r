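# adgcn — multi-omics patient-similarity graph classification for Alzheimer's staging

`adgcn` implements an end-to-end diagnostic pipeline for staging
Alzheimer's disease from three accessible data layers — basic demographic
information (BDI), genotypes summarized as a polygenic risk score (PRS),
and a small panel of blood methylation markers — culminating in **AD-GCN**,
a transductive graph neural network over a patient-similarity graph whose
edge weights come from the correlation of patients' cognitive-score
profiles.

The pipeline stages, each exposed as package functions:

1. **Synthetic cohorts** (`cohort_config()`, `generate_cohort()`): the real
   cohorts in this field are access-restricted, so the package ships a
   seeded generator producing LD-blocked genotypes with sparse causal
   effects, island-annotated beta-value methylation with a planted
   informative subset, label-correlated cognitive scores, and a clinical
   table with missingness — all tied together by a logistic liability.
2. **Genotype QC and association** (`filter_snps()`, `hwe_test()`,
   `genotype_pca()`, `association_scan()`, `clinical_impute_knn()`):
   PLINK-convention filters (missingness > 5%, MAF < 1%, HWE p < 1e-6) and
   per-SNP covariate-adjusted logistic scans producing `SNP A1 BETA SE P N`
   summary statistics.
3. **Polygenic scores** (`clump()`, `prs_pt()`, `ldpred_inf()`,
   `prs_score()`, `nagelkerke_r2()`, `ks_two_sample()`): clumping +
   thresholding with Nagelkerke-R² tuning, and the LDpred infinitesimal
   closed form `w = (D + (M/(N h²))I)⁻¹ β` solved per LD block.
4. **Methylation marker selection** (`select_methylation_markers()` and its
   parts): Welch tests, BH-FDR + CpG-island prefilter, Fisher-score and
   information-gain filters, random-forest ranking, incremental SVM
   evaluation.
5. **Class balancing** (`hybrid_balance()`): borderline-SMOTE oversampling
   of DANGER minority samples combined with borderline undersampling of
   boundary majority samples.
6. **Integration baselines** (`concat_integrate()`, `transform_integrate()`,
   `model_based_integrate()`, `strategy_ladder()`): the three classical
   multi-omics ensemble strategies over the C / C+P / C+P+M block ladder.
7. **AD-GCN** (`adgcn_fit()`, `cross_validate_adgcn()`, `ablate_adgcn()`):
   cosine-similarity edges (kept when similarity > 0.5), kNN expansion,
   cognitive-correlation edge weights, and a two-hidden-layer network —
   a graph-convolution kernel (width 8) then a GraphSAGE kernel (width 3)
   with ReLU, batch normalization and gradient clipping — trained
   full-batch with Adam. `adgcn_fit()` returns a classed model with
   `print`, `summary`, `predict`, `fitted` and `plot` methods.

## A worked example

```r
library(adgcn)

co <- generate_cohort(cohort_config(n_samples = 300, seed = 1))
co
#> Synthetic multi-omics cohort: 300 samples (225/75 per class, IR 3.00)
#>   genotypes: 600 SNPs in 60 LD blocks (8 causal)
#>   methylation: 1500 probes (10 informative, 30% island)
#>   cognitive: 12 scores, target r = 0.40; clinical: 4 BDI columns

blocks <- make_omics_blocks(co, seed = 1)   # QC -> scan -> LDpred PRS -> markers
attr(blocks, "selection")$stage_counts
#>     input prefilter    fisher info_gain        rf     final
#>      1500        10        10        10        10        10

fit <- adgcn_fit(do.call(cbind, blocks), co$cognitive, co$labels,
                 config = train_config(seed = 1))
fit
#> AD-GCN patient-similarity graph classifier
#>   graph: sim_knn_w, 300 nodes, 3304 edges (threshold 0.50, k = 10)
#>   layers: 15 -> 8 (GCN) -> 3 (GraphSAGE) -> 2
#>   trained 300 epochs, final loss 0.0005; 300/300 nodes in training mask

cv <- cross_validate_adgcn(do.call(cbind, blocks), co$cognitive, co$labels,
                           seed = 1)
round(cv$aggregate, 3)
#>       mcc  accuracy precision        f1    g_mean       auc
#>     0.667     0.873     0.744     0.751     0.831     0.877
```

The cross-validated Matthews correlation (here 0.67 on a 300-sample
synthetic cohort) is the headline metric: it rewards balanced accuracy on
both the majority and the minority class. `ablate_adgcn()` reruns the same
folds under the three graph-construction strategies, and
`strategy_ladder()` produces the 3 × 3 ensemble comparison grid.

A thin command-line wrapper lives at `inst/cli/adgcn-omics.R`
(`simulate`, `qc`, `balance`, `run` subcommands over YAML configs), and
`run_pipeline()` executes the whole chain and writes JSON + Markdown
reports.

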