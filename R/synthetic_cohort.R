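#' Synthetic multi-omics cohort configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. Defaults
#' describe a mid-sized case-control staging cohort with an oligogenic
#' genetic architecture (a few strong loci on an LD-blocked panel, in the
#' spirit of APOE-region effects in Alzheimer's disease), a small set of
#' CpG-island marker probes riding a shared epigenetic liability factor,
#' and cognitive scores correlated with the diagnostic label.
#'
#' @param n_samples number of samples.
#' @param class_ratio target majority:minority imbalance ratio (>= 1).
#' @param n_snps SNP panel size.
#' @param n_ld_blocks number of contiguous LD blocks partitioning the panel.
#' @param n_causal_snps number of causal SNPs (effects drawn
#'   `N(0, snp_effect_sd^2)` in log-odds units).
#' @param snp_effect_sd standard deviation of causal log-odds effects.
#' @param maf_range length-2 vector of minor-allele-frequency bounds in (0, 0.5).
#' @param within_block_r latent exchangeable correlation inside an LD block, in \[0, 1).
#' @param geno_missing_rate MCAR genotype missingness rate in \[0, 1).
#' @param n_probes methylation probe count.
#' @param n_informative_probes number of label-informative probes (always
#'   placed on CpG islands so the island prefilter can in principle recover them).
#' @param probe_effect mean beta-value shift per unit of the latent epigenetic
#'   factor, in (0, 1).
#' @param island_fraction fraction of probes annotated as CpG-island probes.
#' @param cognitive_signal target Pearson correlation in \[0, 1\] between each
#'   of the 12 cognitive scores and the label.
#' @param probe_liability_weight weight of the shared epigenetic factor in
#'   the logistic liability (default 3); larger values make the methylation
#'   markers more diagnostic relative to genetics.
#' @param clinical_missing_rate MCAR missingness rate for the clinical table.
#' @param seed integer seed; identical config + seed gives an identical cohort.
#' @param architecture_seed seed for the population-level architecture (MAFs,
#'   causal SNPs and effects, island annotation, informative probe set);
#'   defaults to `seed`. Two cohorts sharing `architecture_seed` but
#'   differing in `seed` are independent samples from the same population —
#'   the external-discovery / target design of polygenic scoring.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 500, class_ratio = 3, n_snps = 600,
                          n_ld_blocks = 60, n_causal_snps = 8,
                          snp_effect_sd = 1.0, maf_range = c(0.05, 0.5),
                          within_block_r = 0.7, geno_missing_rate = 0.02,
                          n_probes = 1500, n_informative_probes = 10,
                          probe_effect = 0.15, island_fraction = 0.3,
                          cognitive_signal = 0.4, clinical_missing_rate = 0.05,
                          probe_liability_weight = 3,
                          seed = 1, architecture_seed = NULL) {
  cfg <- list(n_samples = as.integer(n_samples), class_ratio = class_ratio,
              n_snps = as.integer(n_snps), n_ld_blocks = as.integer(n_ld_blocks),
              n_causal_snps = as.integer(n_causal_snps),
              snp_effect_sd = snp_effect_sd, maf_range = maf_range,
              within_block_r = within_block_r,
              geno_missing_rate = geno_missing_rate,
              n_probes = as.integer(n_probes),
              n_informative_probes = as.integer(n_informative_probes),
              probe_effect = probe_effect, island_fraction = island_fraction,
              cognitive_signal = cognitive_signal,
              clinical_missing_rate = clinical_missing_rate,
              probe_liability_weight = probe_liability_weight,
              seed = as.integer(seed),
              architecture_seed = as.integer(architecture_seed %||% seed))
  if (cfg$n_samples < 10) stop_config("n_samples", "must be >= 10")
  if (cfg$class_ratio < 1) stop_config("class_ratio", "must be >= 1")
  if (cfg$n_causal_snps > cfg$n_snps) stop_config("n_causal_snps", "exceeds n_snps")
  if (cfg$n_informative_probes > cfg$n_probes)
    stop_config("n_informative_probes", "exceeds n_probes")
  if (cfg$n_ld_blocks < 1 || cfg$n_ld_blocks > cfg$n_snps)
    stop_config("n_ld_blocks", "must be in [1, n_snps]")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop_config("maf_range", "must be an increasing pair inside (0, 0.5]")
  if (cfg$within_block_r < 0 || cfg$within_block_r >= 1)
    stop_config("within_block_r", "must be in [0, 1)")
  for (f in c("geno_missing_rate", "island_fraction", "clinical_missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_config(f, "must be in [0, 1]")
  if (cfg$cognitive_signal < 0 || cfg$cognitive_signal > 1)
    stop_config("cognitive_signal", "must be in [0, 1]")
  if (cfg$probe_effect <= 0 || cfg$probe_effect >= 1)
    stop_config("probe_effect", "must be in (0, 1)")
  class(cfg) <- "cohort_config"
  cfg
}

# contiguous block index for p SNPs in b blocks
ld_block_index <- function(n_snps, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_snps))
}

#' Generate LD-blocked genotype dosages
#'
#' Gaussian-copula genotypes: within each contiguous block the two latent
#' haplotype draws of every SNP share an exchangeable correlation
#' `within_block_r`; alleles are obtained by thresholding the latent normals
#' at the SNP's MAF quantile, so marginal dosages are Binomial(2, MAF).
#' Blocks are mutually independent.
#'
#' @inheritParams cohort_config
#' @param within_block_r latent correlation in \[0, 1).
#' @param seed integer seed.
#' @param maf optional per-SNP minor allele frequencies (drawn uniformly
#'   from `maf_range` when `NULL`); supply to sample repeatedly from one
#'   population.
#' @return list with `genotypes` (n_samples x n_snps integer dosages 0/1/2,
#'   SNP columns named `snp0001`...), `maf` (simulated MAFs) and `blocks`
#'   (block index per SNP).
#' @export
generate_ld_blocked_genotypes <- function(n_samples, n_snps, n_ld_blocks,
                                          maf_range = c(0.05, 0.5),
                                          within_block_r = 0.7, seed = 1,
                                          maf = NULL) {
  if (any(maf_range <= 0) || any(maf_range >= 0.5001))
    stop("maf_range must lie inside (0, 0.5]")
  if (within_block_r < 0 || within_block_r >= 1)
    stop("within_block_r must be in [0, 1)")
  blocks <- ld_block_index(n_snps, n_ld_blocks)
  with_seed(seed, {
    if (is.null(maf)) maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    g <- matrix(0L, n_samples, n_snps)
    sr <- sqrt(within_block_r); sn <- sqrt(1 - within_block_r)
    for (b in unique(blocks)) {
      j <- which(blocks == b)
      for (h in 1:2) {                       # two haplotypes per sample
        common <- stats::rnorm(n_samples)
        z <- sr * common +
          sn * matrix(stats::rnorm(n_samples * length(j)), n_samples)
        allele <- sweep(stats::pnorm(z), 2, maf[j], "<")
        g[, j] <- g[, j] + allele
      }
    }
    colnames(g) <- sprintf("snp%04d", seq_len(n_snps))
    list(genotypes = g, maf = maf, blocks = blocks)
  })
}

#' Inject missing-completely-at-random cells
#'
#' @param x a matrix or data.frame.
#' @param rate missingness rate in \[0, 1).
#' @param seed integer seed; the mask is reproducible.
#' @return `x` with cells set to `NA`.
#' @export
inject_missing <- function(x, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  mask <- with_seed(seed, matrix(stats::runif(nr * nc) < rate, nr, nc))
  if (is.data.frame(x)) {
    for (j in seq_len(nc)) x[mask[, j], j] <- NA
  } else {
    x[mask] <- NA
  }
  x
}

#' Generate a synthetic multi-omics staging cohort
#'
#' Draws a cohort with four row-aligned blocks: a clinical table (age, sex,
#' education, marital status, with MCAR missingness), 12 cognitive scores
#' correlated with the label at `cognitive_signal`, LD-blocked genotype
#' dosages with sparse causal effects, and a beta-value methylation matrix in
#' which `n_informative_probes` island probes track a latent epigenetic
#' liability factor. The diagnostic label derives from a logistic liability
#' (causal-SNP dosage effects + the epigenetic factor + logistic noise); the
#' liability intercept is the empirical quantile that yields exactly the
#' requested class ratio.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort`: list with `sample_ids`, `labels`
#'   (0 = milder group, 1 = more-severe group), `clinical`, `cognitive`,
#'   `genotypes`, `methylation`, `probe_meta`, `maf`, `blocks`, `truth`
#'   (causal SNP indices/effects, informative probe indices/shift) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_samples
  # population-level architecture: shared by cohorts with equal architecture_seed
  arch <- with_seed(derive_seed(cfg$architecture_seed, 100L), {
    n_island <- round(cfg$island_fraction * cfg$n_probes)
    island <- logical(cfg$n_probes)
    island[sample.int(cfg$n_probes, n_island)] <- TRUE
    informative <- if (cfg$n_informative_probes > 0) {
      pool <- which(island)
      if (length(pool) < cfg$n_informative_probes)
        stop_config("island_fraction", "leaves too few island probes for the informative set")
      sort(sample(pool, cfg$n_informative_probes))
    } else integer(0)
    list(maf = stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2]),
         causal = sort(sample.int(cfg$n_snps, cfg$n_causal_snps)),
         beta = stats::rnorm(cfg$n_causal_snps, 0, cfg$snp_effect_sd),
         island = island, informative = informative,
         base = ifelse(island, stats::runif(cfg$n_probes, 0.10, 0.40),
                       stats::runif(cfg$n_probes, 0.50, 0.90)))
  })
  gen <- generate_ld_blocked_genotypes(n, cfg$n_snps, cfg$n_ld_blocks,
                                       cfg$maf_range, cfg$within_block_r,
                                       seed = derive_seed(cfg$seed, 1L),
                                       maf = arch$maf)
  with_seed(derive_seed(cfg$seed, 2L), {
    causal <- arch$causal
    beta <- arch$beta
    u <- stats::rnorm(n)                    # latent epigenetic factor
    # the epigenetic factor enters the liability only when informative
    # probes exist (truth bookkeeping: liability terms == truth)
    w_m <- if (cfg$n_informative_probes > 0) cfg$probe_liability_weight else 0
    eta <- as.numeric(gen$genotypes[, causal, drop = FALSE] %*% beta) + w_m * u
    latent <- eta + stats::rlogis(n)
    n_minor <- round(n / (1 + cfg$class_ratio))
    labels <- integer(n)
    labels[order(latent, decreasing = TRUE)[seq_len(n_minor)]] <- 1L

    # --- methylation: island-aware baselines, informative probes ride u ---
    island <- arch$island
    informative <- arch$informative
    base <- arch$base
    meth <- matrix(stats::rnorm(n * cfg$n_probes, 0, 0.05), n, cfg$n_probes)
    meth <- sweep(meth, 2, base, "+")
    if (length(informative) > 0) {
      # informative probes are co-methylated, not copies: each mixes the
      # shared liability factor u with a probe-specific component (rho = 0.6)
      rho <- 0.6
      s <- rho * u + sqrt(1 - rho^2) *
        matrix(stats::rnorm(n * length(informative)), n)
      meth[, informative] <- meth[, informative] + cfg$probe_effect * s
    }
    meth <- pmin(pmax(meth, 0), 1)
    colnames(meth) <- sprintf("cg%06d", seq_len(cfg$n_probes))

    # --- cognitive: |r(score, label)| ~= cognitive_signal per column ---
    # half the battery rises with severity, half falls (CDRSB-like vs
    # MMSE-like directions); heterogeneous signed loadings are what make the
    # sample-pair correlation of score vectors class-informative
    p1 <- mean(labels)
    sd_y <- sqrt(p1 * (1 - p1))
    a <- if (cfg$cognitive_signal >= 1) 1e6 else
      cfg$cognitive_signal / (sd_y * sqrt(1 - cfg$cognitive_signal^2))
    dirs <- rep(c(1, -1), 6)
    # symmetric +/- 1/2 severity coding: both diagnostic groups have coherent
    # cognitive profiles, of opposite orientation
    cog <- matrix(stats::rnorm(n * 12), n, 12) +
      outer(labels - 0.5, a * dirs)
    colnames(cog) <- sprintf("cogscore%02d", 1:12)

    # --- clinical (BDI): weak age shift only, per staging-cohort demographics ---
    clinical <- data.frame(
      age = round(stats::rnorm(n, 73, 7) + 1.5 * labels, 1),
      sex = factor(ifelse(stats::runif(n) < 0.51 - 0.10 * labels, "F", "M")),
      education = pmax(6, round(stats::rnorm(n, 16, 2.5))),
      marital = factor(sample(c("married", "widowed", "divorced", "never"),
                              n, replace = TRUE, prob = c(.6, .2, .15, .05))),
      stringsAsFactors = TRUE)
  })
  clinical <- inject_missing(clinical, cfg$clinical_missing_rate,
                             seed = derive_seed(cfg$seed, 3L))
  # a fully-missing clinical record would be unusable downstream; keep age
  all_gone <- rowSums(!is.na(clinical)) == 0
  if (any(all_gone))
    clinical$age[all_gone] <- round(with_seed(
      derive_seed(cfg$seed, 5L), stats::rnorm(sum(all_gone), 73, 7)), 1)
  genotypes <- inject_missing(gen$genotypes, cfg$geno_missing_rate,
                              seed = derive_seed(cfg$seed, 4L))
  probe_meta <- data.frame(probe = colnames(meth), island = island,
                           p_value = welch_t_pvalues(meth, labels))
  cohort <- structure(list(
    sample_ids = sprintf("S%04d", seq_len(n)),
    labels = labels, clinical = clinical, cognitive = cog,
    genotypes = genotypes, methylation = meth, probe_meta = probe_meta,
    maf = gen$maf, blocks = gen$blocks,
    truth = list(causal_snps = causal, causal_effects = beta,
                 informative_probes = informative,
                 probe_shift = cfg$probe_effect),
    config = cfg), class = "cohort")
  rownames(cohort$clinical) <- cohort$sample_ids
  rownames(cohort$cognitive) <- cohort$sample_ids
  rownames(cohort$genotypes) <- cohort$sample_ids
  rownames(cohort$methylation) <- cohort$sample_ids
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic multi-omics cohort: %d samples (%d/%d per class, IR %.2f)\n",
    "  genotypes: %d SNPs in %d LD blocks (%d causal)\n",
    "  methylation: %d probes (%d informative, %.0f%% island)\n",
    "  cognitive: 12 scores, target r = %.2f; clinical: 4 BDI columns\n"),
    length(x$labels), sum(x$labels == 0), sum(x$labels == 1),
    sum(x$labels == 0) / max(1, sum(x$labels == 1)),
    ncol(x$genotypes), x$config$n_ld_blocks, length(x$truth$causal_snps),
    ncol(x$methylation), length(x$truth$informative_probes),
    100 * mean(x$probe_meta$island), x$config$cognitive_signal))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `clinical.csv`, `cognitive.csv`, `methylation.csv`, `probe_meta.csv`,
#' `labels.csv`, `truth.json` and genotypes as either an uncompressed VCF
#' (unphased GT field) or a dosage CSV.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @param genotype_format `"vcf"` or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("vcf", "csv")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = TRUE)
  w(cohort$clinical, "clinical.csv")
  w(as.data.frame(cohort$cognitive), "cognitive.csv")
  w(as.data.frame(cohort$methylation), "methylation.csv")
  utils::write.csv(cohort$probe_meta, file.path(dir, "probe_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample_id = cohort$sample_ids,
                              label = cohort$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (genotype_format == "vcf") {
    write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  } else {
    w(as.data.frame(cohort$genotypes), "genotypes.csv")
  }
  invisible(dir)
}

#' Write 0/1/2 dosages as a minimal unphased VCF
#'
#' @param genotypes samples x SNPs dosage matrix (NA allowed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  snps <- colnames(genotypes) %||% sprintf("snp%04d", seq_len(ncol(genotypes)))
  samples <- rownames(genotypes) %||% sprintf("S%04d", seq_len(nrow(genotypes)))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    calls <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c("1", j * 100L, snps[j], "A", "G", ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a VCF into a 0/1/2 dosage matrix
#'
#' Parses GT calls (phased or unphased) into alternate-allele dosages;
#' missing calls (`./.`) become `NA`.
#'
#' @param path VCF file.
#' @return samples x SNPs integer matrix.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(s) {
    if (is.na(s) || s %in% c("./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(s, "[/|]")[[1]]))
  })
  t(dose)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `cohort` object (without generator config).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), row.names = 1,
                                    check.names = FALSE)
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  clinical <- rd("clinical.csv")
  clinical$sex <- factor(clinical$sex)
  clinical$marital <- factor(clinical$marital)
  geno <- if (file.exists(file.path(dir, "genotypes.vcf"))) {
    read_vcf_genotypes(file.path(dir, "genotypes.vcf"))
  } else {
    as.matrix(rd("genotypes.csv"))
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(sample_ids = lab$sample_id, labels = as.integer(lab$label),
                 clinical = clinical, cognitive = as.matrix(rd("cognitive.csv")),
                 genotypes = geno, methylation = as.matrix(rd("methylation.csv")),
                 probe_meta = utils::read.csv(file.path(dir, "probe_meta.csv")),
                 truth = truth, config = NULL), class = "cohort")
}
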