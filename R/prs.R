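#' Block-wise LD matrices from genotype dosages
#'
#' Pearson correlation of mean-imputed dosages within each LD block, with a
#' light shrink `(R + eps*I) / (1 + eps)` that keeps the unit diagonal while
#' lifting eigenvalues above `-1e-8`. A constant SNP gets zero off-diagonal
#' correlation by definition.
#'
#' @param genotypes samples x SNPs dosage matrix.
#' @param blocks integer block index per SNP (contiguous partition).
#' @param ridge stabilizing shrink weight (default 1e-6).
#' @return an object of class `ld_blocks`: list with `R` (per-block
#'   correlation matrices, dimnames = SNP ids), `block_of` (named block index)
#'   and `snps`.
#' @export
ld_from_genotypes <- function(genotypes, blocks, ridge = 1e-6) {
  stopifnot(nrow(genotypes) >= 2, length(blocks) == ncol(genotypes))
  snps <- colnames(genotypes) %||% sprintf("snp%04d", seq_len(ncol(genotypes)))
  x <- apply(genotypes, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  colnames(x) <- snps
  Rs <- lapply(sort(unique(blocks)), function(b) {
    j <- which(blocks == b)
    R <- suppressWarnings(stats::cor(x[, j, drop = FALSE]))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    R <- (R + diag(ridge, nrow(R))) / (1 + ridge)
    dimnames(R) <- list(snps[j], snps[j])
    R
  })
  names(Rs) <- as.character(sort(unique(blocks)))
  block_of <- stats::setNames(blocks, snps)
  structure(list(R = Rs, block_of = block_of, snps = snps),
            class = "ld_blocks")
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the smallest-p unclaimed SNP as an index SNP and removes
#' every unclaimed SNP in its LD block with squared correlation at or above
#' `r2_threshold`. Ties on p break lexicographically on SNP id.
#'
#' @param stats a `summary_stats` data.frame (SNPs must be in the LD panel).
#' @param ld an [ld_from_genotypes()] result.
#' @param r2_threshold clumping r-squared (default 0.1).
#' @return character vector of index-SNP ids (clump order).
#' @export
clump <- function(stats, ld, r2_threshold = 0.1) {
  if (nrow(stats) == 0) return(character(0))
  missing <- setdiff(stats$SNP, ld$snps)
  if (length(missing) > 0)
    stop(sprintf("clump: SNPs absent from LD panel: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  ord <- order(stats$P, stats$SNP)
  queue <- stats$SNP[ord]
  claimed <- character(0)
  index <- character(0)
  alive <- stats::setNames(rep(TRUE, length(queue)), queue)
  for (s in queue) {
    if (!alive[[s]]) next
    index <- c(index, s)
    alive[[s]] <- FALSE
    b <- ld$block_of[[s]]
    R <- ld$R[[as.character(b)]]
    mates <- intersect(rownames(R), names(alive)[alive])
    if (length(mates) > 0) {
      r2 <- R[s, mates]^2
      alive[mates[r2 >= r2_threshold]] <- FALSE
    }
  }
  index
}

#' Polygenic score from per-SNP weights
#'
#' `PRS_i = sum_j w_j * dosage_ij`, with missing dosages replaced by the
#' per-SNP mean.
#'
#' @param genotypes samples x SNPs dosage matrix.
#' @param weights named numeric vector keyed by SNP id.
#' @return per-sample score vector.
#' @export
prs_score <- function(genotypes, weights) {
  snps <- names(weights)
  absent <- setdiff(snps, colnames(genotypes))
  if (length(absent) > 0)
    stop(sprintf("prs_score: weights name SNPs absent from genotypes: %s",
                 paste(utils::head(absent, 5), collapse = ", ")))
  if (length(snps) == 0) return(rep(0, nrow(genotypes)))
  x <- genotypes[, snps, drop = FALSE]
  x <- apply(x, 2, function(g) { g[is.na(g)] <- mean(g, na.rm = TRUE); g })
  as.numeric(x %*% weights)
}

#' Nagelkerke pseudo R-squared
#'
#' Rescaled Cox-Snell R² for a logistic model:
#' `R2_CS = 1 - exp(2*(ll0 - ll1)/n)`, divided by its maximum
#' `1 - exp(2*ll0/n)` and clipped to \[0, 1\].
#'
#' @param loglik_full,loglik_null fitted and null log-likelihoods.
#' @param n sample size.
#' @return R² in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_null, n) {
  stopifnot(n >= 1)
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  denom <- 1 - exp(2 * loglik_null / n)
  if (denom <= 0) return(0)
  min(max(r2_cs / denom, 0), 1)
}

#' Nagelkerke R² of a fitted logistic model
#'
#' Fits `label ~ predictors` and the intercept-only null with one
#' consistent logistic solver and returns [nagelkerke_r2()] of the pair.
#'
#' @param labels binary 0/1 vector.
#' @param predictors data.frame or matrix of predictors.
#' @return R² in \[0, 1\].
#' @export
nagelkerke_logistic <- function(labels, predictors) {
  df <- data.frame(y = as.integer(labels), as.data.frame(predictors))
  full <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  null <- suppressWarnings(stats::glm(y ~ 1, data = df, family = stats::binomial()))
  nagelkerke_r2(as.numeric(stats::logLik(full)), as.numeric(stats::logLik(null)),
                length(labels))
}

#' Pruning-and-thresholding polygenic score
#'
#' Clumps the summary statistics against the LD panel, then for each
#' candidate threshold in `p_grid` scores samples with the index SNPs whose
#' association p-value passes, selecting the threshold that maximizes the
#' Nagelkerke R² of `label ~ PRS` on the training samples.
#'
#' @param genotypes,labels training genotypes and binary labels.
#' @param stats discovery `summary_stats`.
#' @param ld [ld_from_genotypes()] LD panel.
#' @param p_grid candidate p-value thresholds (default: 50-point log grid
#'   from 5e-8 to 1).
#' @param r2_threshold clumping r² (default 0.1).
#' @return an object of class `prs_result` with `method = "PT"`, `weights`,
#'   `scores`, `tuning` (`p_t`, `n_snps`) and `r2_nagelkerke`.
#' @export
prs_pt <- function(genotypes, labels, stats, ld,
                   p_grid = exp(seq(log(5e-8), log(1), length.out = 50)),
                   r2_threshold = 0.1) {
  stopifnot(length(p_grid) > 0, all(p_grid > 0), all(p_grid <= 1))
  index <- clump(stats, ld, r2_threshold)
  idx_stats <- stats[match(index, stats$SNP), ]
  if (!any(min(idx_stats$P) <= p_grid))
    stop(sprintf("prs_pt: no SNP passes any threshold (min p = %.3g)",
                 min(idx_stats$P)))
  best <- NULL
  for (pt in sort(p_grid)) {
    sel <- idx_stats[idx_stats$P <= pt, ]
    if (nrow(sel) == 0) next
    w <- stats::setNames(sel$BETA, sel$SNP)
    sc <- prs_score(genotypes, w)
    r2 <- nagelkerke_logistic(labels, data.frame(prs = sc))
    if (is.null(best) || r2 > best$r2_nagelkerke + 1e-12) {
      best <- list(p_t = pt, weights = w, scores = sc, r2_nagelkerke = r2)
    }
  }
  structure(list(method = "PT", weights = best$weights, scores = best$scores,
                 tuning = list(p_t = best$p_t, n_snps = length(best$weights)),
                 r2_nagelkerke = best$r2_nagelkerke),
            class = "prs_result")
}

#' LDpred infinitesimal-model effect shrinkage
#'
#' Analytic posterior-mean joint effects under the infinitesimal model:
#' per LD block, `w = (D + (M/(N*h2)) I)^(-1) beta_marginal`, with `M` the
#' total panel SNP count, `N` the discovery sample size and `D` the block LD
#' matrix. Blocks are solved independently.
#'
#' @param stats discovery `summary_stats` (marginal effects).
#' @param ld [ld_from_genotypes()] LD panel covering the stats SNPs.
#' @param n_gwas discovery sample size N.
#' @param h2 assumed trait heritability in (0, 1].
#' @return named per-SNP weight vector.
#' @export
ldpred_inf <- function(stats, ld, n_gwas, h2 = 0.3) {
  stopifnot(h2 > 0, h2 <= 1, n_gwas > 0)
  M <- nrow(stats)
  lambda <- M / (n_gwas * h2)
  w <- stats::setNames(numeric(M), stats$SNP)
  for (b in unique(ld$block_of[stats$SNP])) {
    snps_b <- stats$SNP[ld$block_of[stats$SNP] == b]
    D <- ld$R[[as.character(b)]][snps_b, snps_b, drop = FALSE]
    beta <- stats$BETA[match(snps_b, stats$SNP)]
    sol <- tryCatch(solve(D + diag(lambda, length(snps_b)), beta),
                    error = function(e)
                      stop(sprintf("ldpred_inf: singular system in block %s", b)))
    w[snps_b] <- sol
  }
  w
}

#' Cross-validated AUC of clinical-only vs clinical-plus-PRS models
#'
#' Stratified k-fold logistic regression on the basic demographic
#' information (BDI) alone and on BDI + PRS, reporting per-fold and mean
#' test AUC for both feature sets.
#'
#' @param clinical_bdi data.frame of BDI columns (factors allowed).
#' @param prs per-sample polygenic score.
#' @param labels binary 0/1 vector.
#' @param n_folds folds (default 5, stratified).
#' @param seed fold seed.
#' @return list with `auc_bdi`, `auc_bdi_prs` (per fold), `mean_auc_bdi`,
#'   `mean_auc_bdi_prs`, `delta` and the `fold_plan`.
#' @export
evaluate_bdi_prs <- function(clinical_bdi, prs, labels, n_folds = 5, seed = 1) {
  stopifnot(nrow(clinical_bdi) == length(labels), length(prs) == length(labels))
  X <- stats::model.matrix(~ ., data = clinical_bdi)[, -1, drop = FALSE]
  plan <- stratified_folds(labels, n_folds, seed)
  auc1 <- auc2 <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- plan$folds[[f]]$train; te <- plan$folds[[f]]$test
    fit_auc <- function(cols) {
      d_tr <- data.frame(y = labels[tr], cols[tr, , drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = d_tr,
                                         family = stats::binomial()))
      pr <- suppressWarnings(
        stats::predict(fit, newdata = data.frame(cols[te, , drop = FALSE]),
                       type = "response"))
      auc_rank(labels[te], pr)
    }
    auc1[f] <- fit_auc(as.data.frame(X))
    auc2[f] <- fit_auc(data.frame(X, prs = prs))
  }
  list(auc_bdi = auc1, auc_bdi_prs = auc2,
       mean_auc_bdi = mean(auc1), mean_auc_bdi_prs = mean(auc2),
       delta = mean(auc2) - mean(auc1), fold_plan = plan)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Maximum ECDF distance `D` with the asymptotic two-sided p-value, used to
#' compare polygenic-score or cognitive-score distributions across groups.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return named vector `c(D, p)`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  c(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Write per-sample polygenic scores as a two-column CSV
#'
#' @param scores per-sample score vector.
#' @param sample_ids matching identifiers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prs <- function(scores, sample_ids, path) {
  stopifnot(length(scores) == length(sample_ids))
  utils::write.csv(data.frame(sample_id = sample_ids, score = scores),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("PRS (%s): %d SNPs, Nagelkerke R2 = %.4f",
              x$method, length(x$weights), x$r2_nagelkerke))
  if (!is.null(x$tuning$p_t)) cat(sprintf(", p_T = %.3g", x$tuning$p_t))
  cat("\n")
  invisible(x)
}
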