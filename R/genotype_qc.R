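#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the expectation from the sample allele frequency. A monomorphic SNP (one
#' allele absent) is untestable and returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts.
#' @return two-sided p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("hwe_test: no genotyped samples")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

snp_stats <- function(genotypes) {
  n <- nrow(genotypes)
  miss <- colMeans(is.na(genotypes))
  af <- colMeans(genotypes, na.rm = TRUE) / 2     # alt-allele frequency
  maf <- pmin(af, 1 - af)
  maf[!is.finite(maf)] <- 0
  hwe_p <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    hwe_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
             sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  data.frame(snp = colnames(genotypes), missing_rate = miss, maf = maf,
             hwe_p = hwe_p, row.names = NULL)
}

#' SNP quality-control filter
#'
#' Drops SNPs with missingness above `max_missing_rate`, minor allele
#' frequency below `min_maf`, or Hardy-Weinberg deviation at `hwe_alpha`
#' (PLINK `--geno/--maf/--hwe` conventions). Rules are applied in that order
#' and each dropped SNP is attributed to the first rule it fails.
#'
#' @param genotypes samples x SNPs dosage matrix in {0, 1, 2, NA}.
#' @param max_missing_rate missingness threshold (default 0.05).
#' @param min_maf MAF threshold (default 0.01).
#' @param hwe_alpha HWE p-value threshold (default 1e-6).
#' @return list with `keep` (logical mask over SNP columns), `report`
#'   (counts dropped per rule) and `stats` (per-SNP missingness/MAF/HWE p).
#' @export
filter_snps <- function(genotypes, max_missing_rate = 0.05, min_maf = 0.01,
                        hwe_alpha = 1e-6) {
  st <- snp_stats(genotypes)
  fail_miss <- st$missing_rate > max_missing_rate
  fail_maf <- !fail_miss & st$maf < min_maf
  fail_hwe <- !fail_miss & !fail_maf & st$hwe_p < hwe_alpha
  keep <- !(fail_miss | fail_maf | fail_hwe)
  if (!any(keep)) stop("filter_snps: all SNPs removed by QC; empty panel")
  list(keep = keep,
       report = c(n_input = ncol(genotypes),
                  dropped_missing = sum(fail_miss),
                  dropped_maf = sum(fail_maf),
                  dropped_hwe = sum(fail_hwe),
                  n_retained = sum(keep)),
       stats = st)
}

#' Genotype principal components
#'
#' Mean-imputes missing dosages per SNP, centers columns, and returns the
#' leading principal-component scores for use as population-structure
#' covariates.
#'
#' @param genotypes QC-passed dosage matrix.
#' @param n_components number of components (default 3).
#' @return samples x components score matrix, columns ordered by decreasing
#'   explained variance.
#' @export
genotype_pca <- function(genotypes, n_components = 3) {
  x <- apply(genotypes, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = min(n_components, min(dim(x))), nv = 0)
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, pos)
  if (k < n_components)
    warning(sprintf("genotype_pca: rank %d < requested %d components", k,
                    n_components))
  if (k == 0) return(matrix(0, nrow(x), n_components))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(genotypes)
  scores
}

#' Per-SNP covariate-adjusted association scan
#'
#' Logistic regression of the binary label on each SNP's dosage plus shared
#' covariates; reports the dosage term's log-odds effect, standard error and
#' Wald p-value in PLINK summary-statistics form. Non-converging or
#' quasi-separated fits are flagged and excluded.
#'
#' @param genotypes dosage matrix (missing dosages mean-imputed per SNP).
#' @param labels binary 0/1 vector.
#' @param covariates optional numeric matrix/data.frame, row-aligned.
#' @return a `data.frame` of class `summary_stats` with columns
#'   `SNP A1 BETA SE P N`; flagged SNP ids in `attr(, "flagged")`.
#' @export
association_scan <- function(genotypes, labels, covariates = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(nrow(genotypes) == n)
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  snps <- colnames(genotypes) %||% sprintf("snp%04d", seq_len(ncol(genotypes)))
  rows <- vector("list", ncol(genotypes))
  flagged <- character(0)
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    X <- if (is.null(cv)) cbind(dose = g) else cbind(dose = g, cv)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, X), labels,
                                      family = stats::binomial())),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    if (ok) {
      # Wald se from the Fisher information at the fit
      w <- fit$weights
      XtWX <- crossprod(cbind(1, X) * sqrt(w))
      cov_b <- tryCatch(solve(XtWX), error = function(e) NULL)
      ok <- !is.null(cov_b) && is.finite(cov_b[2, 2]) && cov_b[2, 2] > 0
      if (ok) {
        beta <- fit$coefficients[2]
        se <- sqrt(cov_b[2, 2])
        ok <- is.finite(beta) && abs(beta) < 20 && se < 100
      }
    }
    if (!ok) {
      flagged <- c(flagged, snps[j])
      rows[[j]] <- NULL
      next
    }
    p <- 2 * stats::pnorm(-abs(beta / se))
    rows[[j]] <- data.frame(SNP = snps[j], A1 = "G", BETA = unname(beta),
                            SE = unname(se), P = max(p, .Machine$double.xmin),
                            N = n)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Fixed-effect inverse-variance meta-analysis of summary statistics
#'
#' Combines per-SNP effects from several association scans (matched on
#' `SNP` and `A1`) with inverse-variance weights.
#'
#' @param ... two or more `summary_stats` data.frames.
#' @return a pooled `summary_stats` data.frame over the SNPs shared by all
#'   inputs.
#' @export
meta_fixed <- function(...) {
  stats_list <- list(...)
  stopifnot(length(stats_list) >= 2)
  ids <- Reduce(intersect, lapply(stats_list, function(s) s$SNP))
  rows <- lapply(ids, function(id) {
    recs <- lapply(stats_list, function(s) s[s$SNP == id, ])
    a1 <- recs[[1]]$A1
    if (!all(vapply(recs, function(r) identical(r$A1, a1), logical(1))))
      stop(sprintf("meta_fixed: effect-allele mismatch at %s", id))
    w <- vapply(recs, function(r) 1 / r$SE^2, numeric(1))
    b <- vapply(recs, function(r) r$BETA, numeric(1))
    beta <- sum(w * b) / sum(w)
    se <- sqrt(1 / sum(w))
    data.frame(SNP = id, A1 = a1, BETA = beta, SE = se,
               P = 2 * stats::pnorm(-abs(beta / se)),
               N = sum(vapply(recs, function(r) r$N, numeric(1))))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write / read PLINK-dialect summary statistics
#'
#' Whitespace-delimited table with header `SNP A1 BETA SE P N`.
#'
#' @param stats a `summary_stats` data.frame.
#' @param path file path.
#' @return `path` (writer) or the parsed `summary_stats` (reader).
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  out <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "BETA", "SE", "P")
  if (!all(need %in% names(out)))
    stop("summary statistics must carry columns SNP A1 BETA SE P")
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' K-nearest-neighbour imputation of a clinical table
#'
#' Each missing cell is filled from the `k` complete-case rows nearest in
#' Euclidean distance over the standardized numeric columns observed in the
#' target row: numeric cells take the neighbour mean, categorical cells the
#' neighbour mode.
#'
#' @param clinical a data.frame with numeric and/or factor columns.
#' @param k neighbour count (default 5).
#' @return the completed data.frame.
#' @export
clinical_impute_knn <- function(clinical, k = 5) {
  stopifnot(k >= 1)
  if (!anyNA(clinical)) return(clinical)
  if (any(rowSums(!is.na(clinical)) == 0))
    stop("clinical_impute_knn: a row has all cells missing")
  num_cols <- which(vapply(clinical, is.numeric, logical(1)))
  num <- as.matrix(clinical[, num_cols, drop = FALSE])
  mu <- colMeans(num, na.rm = TRUE)
  sd_ <- apply(num, 2, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  z <- sweep(sweep(num, 2, mu), 2, sd_, "/")
  complete <- which(stats::complete.cases(clinical))
  if (length(complete) < 1)
    stop("clinical_impute_knn: needs at least one complete row")
  k <- min(k, length(complete))
  out <- clinical
  for (i in which(!stats::complete.cases(clinical))) {
    obs <- which(!is.na(z[i, ]))
    d <- if (length(obs) == 0) {
      rep(0, length(complete))       # no numeric info: all neighbours tie
    } else {
      sqrt(colSums((t(z[complete, obs, drop = FALSE]) - z[i, obs])^2))
    }
    nb <- complete[order(d, complete)][seq_len(k)]
    for (jn in names(clinical)[as.logical(is.na(clinical[i, ]))]) {
      vals <- clinical[nb, jn]
      out[i, jn] <- if (is.numeric(vals)) mean(vals) else
        names(sort(table(vals), decreasing = TRUE))[1]
    }
  }
  out
}
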