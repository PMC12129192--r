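# Vectorized per-probe Welch two-sample t-test p-values (two-sided).
welch_t_pvalues <- function(beta, labels) {
  labels <- as.integer(labels)
  i0 <- labels == 0; i1 <- labels == 1
  n0 <- sum(i0); n1 <- sum(i1)
  stopifnot(n0 >= 2, n1 >= 2)
  m0 <- colMeans(beta[i0, , drop = FALSE]); m1 <- colMeans(beta[i1, , drop = FALSE])
  v0 <- apply(beta[i0, , drop = FALSE], 2, stats::var)
  v1 <- apply(beta[i1, , drop = FALSE], 2, stats::var)
  se2 <- v0 / n0 + v1 / n1
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate probes: zero variance in both groups
  degen <- se2 == 0
  p[degen & (m0 == m1)] <- 1
  p[degen & (m0 != m1)] <- .Machine$double.xmin
  p[!is.finite(p)] <- 1
  unname(p)
}

#' Per-probe differential methylation test
#'
#' Welch two-sample t-test of beta values between the two label groups,
#' returning two-sided p-values. Probes with zero variance in both groups
#' and equal means get p = 1.
#'
#' @param beta samples x probes matrix in \[0, 1\].
#' @param labels binary 0/1 vector (>= 2 samples per class).
#' @return per-probe p-value vector.
#' @export
differential_probe_test <- function(beta, labels) {
  welch_t_pvalues(as.matrix(beta), labels)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment `q_i = min_{j: p_(j) >= p_(i)} p_(j)*m/j`, capped
#' at 1 and order-preserving.
#'
#' @param p_values p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' KNN imputation of a beta matrix
#'
#' Missing beta values are replaced by the mean over the `k` sample rows
#' nearest in Euclidean distance on jointly observed probes; output is
#' clipped to \[0, 1\]. Probes missing in every sample are dropped with a
#' warning.
#'
#' @param beta samples x probes matrix with `NA` gaps.
#' @param k neighbour count (default 100, capped at n-1).
#' @return completed beta matrix.
#' @export
knn_impute_beta <- function(beta, k = 100) {
  beta <- as.matrix(beta)
  stopifnot(k >= 1)
  all_missing <- colSums(!is.na(beta)) == 0
  if (any(all_missing)) {
    warning(sprintf("knn_impute_beta: dropping %d probes missing in all samples",
                    sum(all_missing)))
    beta <- beta[, !all_missing, drop = FALSE]
  }
  if (!anyNA(beta)) return(pmin(pmax(beta, 0), 1))
  n <- nrow(beta)
  k <- min(k, n - 1)
  for (i in which(rowSums(is.na(beta)) > 0)) {
    obs_i <- !is.na(beta[i, ])
    d <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      shared <- obs_i & !is.na(beta[j, ])
      if (!any(shared)) return(Inf)
      sqrt(mean((beta[i, shared] - beta[j, shared])^2))
    }, numeric(1))
    nb <- order(d)[seq_len(k)]
    for (jp in which(is.na(beta[i, ]))) {
      vals <- beta[nb, jp]
      beta[i, jp] <- mean(vals, na.rm = TRUE)
    }
  }
  # any cell still NA (neighbours all missing) falls back to the probe mean
  if (anyNA(beta)) {
    pm <- colMeans(beta, na.rm = TRUE)
    idx <- which(is.na(beta), arr.ind = TRUE)
    beta[idx] <- pm[idx[, 2]]
  }
  pmin(pmax(beta, 0), 1)
}

#' FDR + CpG-island probe prefilter
#'
#' Retains probes passing the BH q-value threshold and (optionally) located
#' on CpG islands.
#'
#' @param q_values per-probe BH q-values.
#' @param island per-probe logical island flag.
#' @param q_max q-value cut (default 0.001, strict `<`).
#' @param islands_only require the island flag (default TRUE).
#' @return logical keep mask.
#' @export
prefilter_probes <- function(q_values, island, q_max = 0.001,
                             islands_only = TRUE) {
  keep <- q_values < q_max
  if (islands_only) keep <- keep & island
  if (!any(keep))
    stop(sprintf(paste0("prefilter_probes: no probe survives q < %g",
                        if (islands_only) " on islands" else "",
                        "; consider relaxing thresholds"), q_max))
  keep
}

#' Fisher score of features against a binary label
#'
#' `F_j = sum_c n_c (mu_cj - mu_j)^2 / (sum_c n_c sigma2_cj + eps)` with a
#' small guard `eps = 1e-12`; large scores mean small within-class and large
#' between-class variance.
#'
#' @param X samples x features matrix.
#' @param y binary 0/1 labels.
#' @return nonnegative per-feature score vector.
#' @export
fisher_score <- function(X, y) {
  X <- as.matrix(X); y <- as.integer(y)
  mu <- colMeans(X)
  num <- den <- 0
  for (cl in c(0L, 1L)) {
    idx <- y == cl
    nc <- sum(idx)
    mc <- colMeans(X[idx, , drop = FALSE])
    vc <- apply(X[idx, , drop = FALSE], 2, stats::var)
    vc[!is.finite(vc)] <- 0
    num <- num + nc * (mc - mu)^2
    den <- den + nc * vc
  }
  unname(num / (den + 1e-12))
}

#' Top-quantile feature mask
#'
#' Keeps the `ceiling(keep_top * m)` highest-scoring features; ties at the
#' cut break by feature order.
#'
#' @param scores per-feature scores.
#' @param keep_top retained fraction in (0, 1\] (default 0.25).
#' @return logical mask.
#' @export
top_quantile_mask <- function(scores, keep_top = 0.25) {
  stopifnot(keep_top > 0, keep_top <= 1)
  m <- length(scores)
  n_keep <- ceiling(keep_top * m)
  keep <- logical(m)
  keep[order(-scores, seq_len(m))[seq_len(n_keep)]] <- TRUE
  keep
}

entropy_bits <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Single-threshold (decision-stump) information gain
#'
#' `IG = H(y) - min_t weighted H(y | x <= t, x > t)` over thresholds at the
#' midpoints of sorted unique feature values, with entropies in bits. A
#' constant feature has IG = 0.
#'
#' @param x numeric feature.
#' @param y binary labels.
#' @return information gain in bits.
#' @export
stump_information_gain <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) < 2) return(0)
  h0 <- entropy_bits(y)
  n <- length(y)
  thresholds <- (ux[-1] + ux[-length(ux)]) / 2
  hmin <- min(vapply(thresholds, function(t) {
    left <- x <= t
    mean(left) * entropy_bits(y[left]) + mean(!left) * entropy_bits(y[!left])
  }, numeric(1)))
  max(h0 - hmin, 0)
}

#' Random-forest importance ranking
#'
#' Ranks features by mean impurity-decrease importance from a seeded random
#' forest; ties break by feature order.
#'
#' @param X samples x features matrix (named columns).
#' @param y binary labels.
#' @param n_top number of features to return (default 50, capped at m).
#' @param n_trees forest size (default 500).
#' @param seed forest seed.
#' @return data.frame `feature`, `importance`, `rank` (best first).
#' @export
rf_rank <- function(X, y, n_top = 50, n_trees = 500, seed = 1) {
  X <- as.data.frame(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  n_top <- min(n_top, ncol(X))
  fit <- ranger::ranger(x = X, y = factor(y), num.trees = n_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- fit$variable.importance
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = colnames(X)[ord], importance = unname(imp[ord]),
             rank = seq_along(ord))[seq_len(n_top), ]
}

#' Incremental SVM evaluation over ranked features
#'
#' For each prefix size k of the ranked feature list, runs stratified k-fold
#' cross-validation of an RBF support-vector classifier on the first k
#' features and reports G-mean, accuracy, precision and F1 per k.
#'
#' @param X_ranked samples x features matrix, columns in rank order.
#' @param y binary labels.
#' @param n_folds folds (default 5).
#' @param seed fold seed.
#' @return data.frame with one row per prefix size k.
#' @export
incremental_svm_eval <- function(X_ranked, y, n_folds = 5, seed = 1) {
  X_ranked <- as.matrix(X_ranked)
  plan <- stratified_folds(y, n_folds, seed)
  res <- lapply(seq_len(ncol(X_ranked)), function(k) {
    per_fold <- t(vapply(seq_along(plan$folds), function(fi) {
      fd <- plan$folds[[fi]]
      with_seed(derive_seed(seed, k * 100L + fi), {
        Xtr <- X_ranked[fd$train, seq_len(k), drop = FALSE]
        Xte <- X_ranked[fd$test, seq_len(k), drop = FALSE]
        fit <- suppressWarnings(
          e1071::svm(x = Xtr, y = factor(y[fd$train], levels = c(0, 1))))
        pred <- as.integer(as.character(stats::predict(fit, Xte)))
        classification_metrics(y[fd$test], pred)[c("g_mean", "accuracy",
                                                   "precision", "f1")]
      })
    }, numeric(4)))
    c(k = k, colMeans(per_fold))
  })
  as.data.frame(do.call(rbind, res))
}

#' Full methylation marker-selection cascade
#'
#' Implements the marker pipeline: KNN beta imputation, per-probe Welch
#' differential test with BH correction, the `q < q_max` + CpG-island
#' prefilter, hybrid borderline balancing of the reduced panel, Fisher-score
#' top-quantile filter, removal of zero-information-gain probes, random-forest
#' ranking of the survivors, and selection of the top `n_final` probes.
#' Filters and the forest see only balanced data; the returned matrix holds
#' the original (unbalanced) samples on the selected probes.
#'
#' @param beta samples x probes beta matrix.
#' @param labels binary 0/1 labels.
#' @param island per-probe island flag.
#' @param q_max BH q cut (default 0.001).
#' @param keep_top Fisher-score quantile (default 0.25).
#' @param n_rf random-forest shortlist size (default 50).
#' @param n_final final marker count (default 10).
#' @param k_impute KNN imputation neighbours (default 100).
#' @param seed seed for balancing and the forest.
#' @return list with `selected` (probe names), `ranking` (RF table),
#'   `q_values`, `stage_counts` and `balance` (the [hybrid_balance()] summary).
#' @export
select_methylation_markers <- function(beta, labels, island, q_max = 0.001,
                                       keep_top = 0.25, n_rf = 50,
                                       n_final = 10, k_impute = 100, seed = 1) {
  beta <- knn_impute_beta(as.matrix(beta), k = k_impute)
  p <- differential_probe_test(beta, labels)
  q <- bh_adjust(p)
  keep <- prefilter_probes(q, island, q_max = q_max)
  panel <- beta[, keep, drop = FALSE]
  bal <- hybrid_balance(panel, labels, seed = derive_seed(seed, 11L))
  Xb <- bal$X_out; yb <- bal$y_out
  fs <- fisher_score(Xb, yb)
  # the quantile cut never shrinks the panel below the RF shortlist size,
  # so a highly selective prefilter cannot starve the embedded stage
  keep_frac <- max(keep_top, min(1, n_rf / length(fs)))
  m1 <- top_quantile_mask(fs, keep_frac)
  ig <- vapply(which(m1), function(j) stump_information_gain(Xb[, j], yb),
               numeric(1))
  cand <- which(m1)[ig > 0]
  if (length(cand) == 0) cand <- which(m1)   # all-zero IG: fall back to Fisher set
  ranking <- rf_rank(Xb[, cand, drop = FALSE], yb,
                     n_top = min(n_rf, length(cand)),
                     seed = derive_seed(seed, 12L))
  selected <- ranking$feature[seq_len(min(n_final, nrow(ranking)))]
  list(selected = selected,
       markers = beta[, selected, drop = FALSE],
       ranking = ranking, q_values = q,
       stage_counts = c(input = ncol(beta), prefilter = ncol(panel),
                        fisher = sum(m1), info_gain = length(cand),
                        rf = nrow(ranking), final = length(selected)),
       balance = bal[c("n_synthetic", "n_removed", "ir_before", "ir_after")])
}
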