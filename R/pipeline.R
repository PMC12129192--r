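# Pipeline glue: block assembly from a cohort, end-to-end run, reporting.

# Numeric 4-column BDI encoding (age, sex 0/1, education, marital code).
encode_bdi <- function(clinical) {
  cl <- clinical_impute_knn(clinical, k = 5)
  cbind(age = as.numeric(cl$age),
        sex = as.integer(cl$sex == levels(cl$sex)[1]),
        education = as.numeric(cl$education),
        marital = as.integer(cl$marital))
}

#' Assemble the three integration blocks from a cohort
#'
#' Builds the `clinical_bdi` (4 numeric columns), `prs` (1 column) and
#' `methylation_top` (top-10 marker probes) blocks. The polygenic score is
#' trained on an independent discovery cohort (association scan with
#' age/sex/education and three genotype principal components as covariates,
#' QC-filtered panel, LDpred-infinitesimal shrinkage) and applied to the
#' target cohort, mirroring an external-discovery design.
#'
#' @param cohort target [generate_cohort()] cohort.
#' @param discovery discovery cohort; defaults to a cohort drawn from the
#'   same configuration with an independent seed.
#' @param h2 assumed heritability for LDpred-inf (default 0.3).
#' @param n_markers methylation markers retained (default 10).
#' @param q_max BH q cut of the probe prefilter (default 0.001).
#' @param seed stage seed.
#' @return named list of blocks with the PRS result, marker selection and
#'   QC report attached as attributes.
#' @export
make_omics_blocks <- function(cohort, discovery = NULL, h2 = 0.3,
                              n_markers = 10, q_max = 0.001, seed = 1) {
  if (is.null(discovery)) {
    if (is.null(cohort$config))
      stop("make_omics_blocks: supply a discovery cohort for file-loaded cohorts")
    dcfg <- cohort$config
    dcfg$seed <- derive_seed(dcfg$seed, 9901L)   # new samples, same population
    dcfg$n_samples <- max(dcfg$n_samples, 800L)  # GWAS-scale discovery
    discovery <- generate_cohort(dcfg)
  }
  qc <- filter_snps(discovery$genotypes)
  kept <- colnames(discovery$genotypes)[qc$keep]
  G_disc <- discovery$genotypes[, kept, drop = FALSE]
  covs <- cbind(encode_bdi(discovery$clinical)[, c("age", "sex", "education")],
                genotype_pca(G_disc, 3))
  scan <- association_scan(G_disc, discovery$labels, covs)
  blocks_idx <- discovery$blocks[match(scan$SNP, colnames(discovery$genotypes))]
  ld <- ld_from_genotypes(G_disc[, scan$SNP, drop = FALSE], blocks_idx)
  weights <- ldpred_inf(scan, ld, n_gwas = nrow(G_disc), h2 = h2)
  prs <- prs_score(cohort$genotypes[, names(weights), drop = FALSE], weights)
  sel <- select_methylation_markers(cohort$methylation, cohort$labels,
                                    cohort$probe_meta$island,
                                    q_max = q_max, n_final = n_markers,
                                    seed = derive_seed(seed, 2L))
  blocks <- list(clinical_bdi = encode_bdi(cohort$clinical),
                 prs = matrix(prs, ncol = 1, dimnames = list(NULL, "prs")),
                 methylation_top = sel$markers)
  attr(blocks, "qc_report") <- qc$report
  attr(blocks, "summary_stats") <- scan
  attr(blocks, "weights") <- weights
  attr(blocks, "selection") <- sel[c("selected", "stage_counts", "balance")]
  blocks
}

#' Export a graph specification as plain text
#'
#' Writes the weighted edge list as TSV (`i`, `j`, `weight`) plus a JSON
#' provenance sidecar.
#'
#' @param graph a [build_graph()] result.
#' @param path_prefix output prefix; writes `<prefix>.edges.tsv` and
#'   `<prefix>.json`.
#' @return the TSV path, invisibly.
#' @export
write_graph_spec <- function(graph, path_prefix) {
  tsv <- paste0(path_prefix, ".edges.tsv")
  utils::write.table(
    data.frame(i = graph$edges[, 1], j = graph$edges[, 2],
               weight = graph$weights),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(graph[c("n_nodes", "strategy", "sim_threshold", "k")],
                       paste0(path_prefix, ".json"), auto_unbox = TRUE)
  invisible(tsv)
}

#' Run the full diagnostic pipeline from a configuration
#'
#' Executes simulate -> genotype QC -> PRS (LDpred-inf, P+T, clinical
#' evaluation, KS comparison) -> methylation marker selection (with hybrid
#' balancing) -> ensemble block ladder -> AD-GCN ablation, and writes a
#' consolidated JSON + Markdown report.
#'
#' @param config a YAML file path or an equivalent nested list with optional
#'   `simulate` (arguments of [cohort_config()]), `prs` (`h2`), `adgcn`
#'   (`k`, `sim_threshold`, `epochs`, `strategy`), `n_folds` and `seed`
#'   entries.
#' @param out_dir output directory for reports (created; default `tempdir()`
#'   subdirectory).
#' @return the report list, invisibly; written to `report.json` and
#'   `report.md` under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = file.path(tempdir(), "adgcn_run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  n_folds <- config$n_folds %||% 5L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% seed
  cfg <- do.call(cohort_config, sim_args)
  cohort <- generate_cohort(cfg)
  blocks <- make_omics_blocks(cohort, h2 = config$prs$h2 %||% 0.3,
                              q_max = config$methylation$q_max %||% 0.001,
                              seed = seed)
  stats <- attr(blocks, "summary_stats")
  prs_vec <- as.numeric(blocks$prs)

  # P+T on the target against the discovery stats, via the target LD panel
  ld_t <- ld_from_genotypes(
    cohort$genotypes[, stats$SNP, drop = FALSE],
    cohort$blocks[match(stats$SNP, colnames(cohort$genotypes))])
  pt <- prs_pt(cohort$genotypes[, stats$SNP, drop = FALSE], cohort$labels,
               stats, ld_t)
  bdi_eval <- evaluate_bdi_prs(cohort$clinical |> clinical_impute_knn(),
                               prs_vec, cohort$labels,
                               n_folds = n_folds, seed = seed)
  ks <- ks_two_sample(prs_vec[cohort$labels == 1], prs_vec[cohort$labels == 0])

  ladder <- strategy_ladder(blocks, cohort$labels, n_folds = n_folds,
                            seed = seed)
  features <- do.call(cbind, blocks)
  acfg <- train_config(epochs = config$adgcn$epochs %||% 300, seed = seed)
  ablation <- ablate_adgcn(features, cohort$cognitive, cohort$labels,
                           config = acfg, n_folds = n_folds, seed = seed,
                           sim_threshold = config$adgcn$sim_threshold %||% 0.5,
                           k = config$adgcn$k %||% 10)

  report <- list(
    config = config,
    cohort = list(n = length(cohort$labels),
                  ir = unname(imbalance_ratio(cohort$labels))),
    qc = as.list(attr(blocks, "qc_report")),
    prs = list(ldpred_nagelkerke = nagelkerke_logistic(
                 cohort$labels, data.frame(prs = prs_vec)),
               pt_nagelkerke = pt$r2_nagelkerke,
               pt_p_threshold = pt$tuning$p_t, pt_n_snps = pt$tuning$n_snps,
               auc_bdi = bdi_eval$mean_auc_bdi,
               auc_bdi_prs = bdi_eval$mean_auc_bdi_prs,
               ks_D = unname(ks["D"]), ks_p = unname(ks["p"])),
    methylation = attr(blocks, "selection"),
    ensemble = ladder[, c("strategy", "ladder", "mcc", "accuracy",
                          "precision")],
    adgcn = ablation$comparison)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  invisible(report)
}

format_report_md <- function(rep) {
  fmt_df <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(
        vapply(r, function(v) {
          vn <- suppressWarnings(as.numeric(v))
          if (is.na(vn)) as.character(v) else format(round(vn, 4))
        }, character(1)), collapse = " | ")))
  }
  c("# Multi-omics diagnostic pipeline report", "",
    sprintf("Cohort: n = %d, imbalance ratio %.2f", rep$cohort$n, rep$cohort$ir),
    sprintf("QC: %d/%d SNPs retained", rep$qc$n_retained, rep$qc$n_input), "",
    "## Polygenic risk scores",
    sprintf("- LDpred-inf Nagelkerke R2: %.4f", rep$prs$ldpred_nagelkerke),
    sprintf("- P+T Nagelkerke R2: %.4f (p_T = %.3g, %d SNPs)",
            rep$prs$pt_nagelkerke, rep$prs$pt_p_threshold, rep$prs$pt_n_snps),
    sprintf("- CV AUC: BDI %.3f, BDI+PRS %.3f", rep$prs$auc_bdi,
            rep$prs$auc_bdi_prs),
    sprintf("- KS(PRS | class): D = %.3f, p = %.3g", rep$prs$ks_D, rep$prs$ks_p),
    "", "## Methylation markers",
    sprintf("- pipeline: %s", paste(names(rep$methylation$stage_counts),
                                    rep$methylation$stage_counts,
                                    sep = "=", collapse = ", ")),
    sprintf("- balancing: IR %.2f -> %.2f", rep$methylation$balance$ir_before,
            rep$methylation$balance$ir_after),
    "", "## Ensemble integration ladder", fmt_df(rep$ensemble),
    "", "## AD-GCN ablation", fmt_df(rep$adgcn))
}
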