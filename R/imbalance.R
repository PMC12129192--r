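#' Imbalance ratio
#'
#' `IR = n_majority / n_minority >= 1` for a two-class label vector.
#'
#' @param y binary label vector (both classes present).
#' @return the imbalance ratio.
#' @export
imbalance_ratio <- function(y) {
  tab <- table(y)
  if (length(tab) != 2) stop("imbalance_ratio: need exactly two classes present")
  max(tab) / min(tab)
}

pairwise_dist <- function(X) {
  as.matrix(stats::dist(X))
}

minority_class <- function(y) {
  tab <- table(y)
  names(tab)[which.min(tab)]
}

#' Borderline neighbourhood taxonomy
#'
#' For each minority sample, counts majority samples among its `m` nearest
#' neighbours (Euclidean, self excluded): all `m` majority = NOISE, at least
#' `m/2` = DANGER, otherwise SAFE. A majority sample is boundary-flagged iff
#' it appears among the `m` nearest neighbours of at least one DANGER
#' minority sample.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param m neighbourhood size (default 5).
#' @return list with `category` (per-minority factor, names = row indices),
#'   `minority_idx`, `boundary_majority` (indices), `danger_hits`
#'   (per-majority count of DANGER neighbourhoods containing it) and `m`.
#' @export
classify_boundary <- function(X, y, m = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(m < n)
  mc <- minority_class(y)
  min_idx <- which(y == mc)
  maj_idx <- which(y != mc)
  D <- pairwise_dist(X)
  diag(D) <- Inf                                      # self never a neighbour
  category <- character(length(min_idx))
  hits <- stats::setNames(integer(length(maj_idx)), maj_idx)
  for (ii in seq_along(min_idx)) {
    i <- min_idx[ii]
    nb <- order(D[i, ], seq_len(n))[seq_len(m)]
    n_maj <- sum(y[nb] != mc)
    category[ii] <- if (n_maj == m) "NOISE" else
      if (n_maj >= m / 2) "DANGER" else "SAFE"
    if (category[ii] == "DANGER") {
      mj <- as.character(nb[y[nb] != mc])
      hits[mj] <- hits[mj] + 1L
    }
  }
  list(category = stats::setNames(factor(category,
                                         levels = c("SAFE", "DANGER", "NOISE")),
                                  min_idx),
       minority_idx = min_idx,
       boundary_majority = maj_idx[hits[as.character(maj_idx)] > 0],
       danger_hits = hits, m = m)
}

#' Borderline-SMOTE synthetic minority samples
#'
#' Each synthetic row interpolates a DANGER minority sample `d` towards one
#' of its `k` nearest minority neighbours `nn`:
#' `d + u * (nn - d)`, `u ~ Uniform(0, 1)`. Generation cycles over the
#' DANGER set until `n_new` rows exist. NOISE minority samples never seed
#' synthesis.
#'
#' @param X,y data matrix and binary labels.
#' @param m boundary neighbourhood size (default 5).
#' @param k minority-neighbour pool size (default 5).
#' @param n_new number of synthetic rows.
#' @param seed RNG seed.
#' @param u_override optional fixed interpolation weight (testing hook).
#' @return matrix of `n_new` synthetic minority rows (zero rows with a
#'   warning when no DANGER sample exists).
#' @export
borderline_smote <- function(X, y, m = 5, k = 5, n_new, seed = 1,
                             u_override = NULL) {
  X <- as.matrix(X)
  bl <- classify_boundary(X, y, m)
  danger <- as.integer(names(bl$category)[bl$category == "DANGER"])
  if (length(danger) == 0) {
    warning("borderline_smote: no DANGER minority samples; nothing to synthesize")
    return(X[integer(0), , drop = FALSE])
  }
  min_idx <- bl$minority_idx
  k <- min(k, length(min_idx) - 1)
  stopifnot(k >= 1)
  D <- pairwise_dist(X[min_idx, , drop = FALSE])
  diag(D) <- Inf
  out <- matrix(NA_real_, n_new, ncol(X))
  with_seed(seed, {
    for (s in seq_len(n_new)) {
      d_global <- danger[(s - 1) %% length(danger) + 1]
      d_local <- match(d_global, min_idx)
      nb_local <- order(D[d_local, ], seq_along(min_idx))[seq_len(k)]
      nn_local <- nb_local[sample.int(length(nb_local), 1)]
      u <- if (is.null(u_override)) stats::runif(1) else u_override
      out[s, ] <- X[d_global, ] + u * (X[min_idx[nn_local], ] - X[d_global, ])
    }
  })
  colnames(out) <- colnames(X)
  out
}

#' Borderline undersampling of majority samples
#'
#' Removes `ceiling(fraction * n_boundary)` boundary-flagged majority
#' samples, preferring those appearing in the most DANGER-minority
#' neighbourhoods (ties broken by a seeded shuffle). Non-boundary majority
#' samples are never removed.
#'
#' @inheritParams borderline_smote
#' @param fraction fraction of boundary majority to remove, in \[0, 1\].
#' @param n_remove optional absolute removal count overriding `fraction`
#'   (capped at the boundary set size).
#' @return logical removal mask over the rows of `X`.
#' @export
borderline_undersample <- function(X, y, m = 5, fraction = 0.5, seed = 1,
                                   n_remove = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  bl <- classify_boundary(as.matrix(X), y, m)
  boundary <- bl$boundary_majority
  n_rm <- if (is.null(n_remove)) ceiling(fraction * length(boundary)) else
    min(n_remove, length(boundary))
  mask <- logical(nrow(X))
  if (n_rm == 0 || length(boundary) == 0) return(mask)
  hits <- bl$danger_hits[as.character(boundary)]
  ord <- with_seed(seed, order(-hits, stats::runif(length(boundary))))
  mask[boundary[ord][seq_len(n_rm)]] <- TRUE
  mask
}

#' Hybrid borderline balancing
#'
#' Two-stage class balancing: first remove boundary-flagged majority samples
#' (capped at half the majority-minority gap), then oversample DANGER
#' minority samples with borderline-SMOTE until the imbalance ratio falls to
#' `target_ir` (within 5 percent). Synthesis sees the cleaned boundary:
#' DANGER membership is recomputed after removal.
#'
#' @param X samples x features matrix.
#' @param y binary 0/1 labels.
#' @param target_ir target imbalance ratio >= 1 (default 1.0).
#' @param m,k borderline-SMOTE neighbourhood sizes (default 5, 5).
#' @param seed RNG seed.
#' @return an object of class `balance_result`: `X_out`, `y_out`,
#'   `n_synthetic`, `n_removed`, `ir_before`, `ir_after`, `synthetic_rows`
#'   (index range of appended rows).
#' @export
hybrid_balance <- function(X, y, target_ir = 1.0, m = 5, k = 5, seed = 1) {
  stopifnot(target_ir >= 1)
  X <- as.matrix(X); y <- as.integer(y)
  ir_before <- imbalance_ratio(y)
  mc <- as.integer(minority_class(y))
  n_min <- sum(y == mc); n_maj <- sum(y != mc)
  out_X <- X; out_y <- y
  n_removed <- 0L
  if (ir_before > target_ir) {
    cap <- floor((n_maj - n_min) / 2)
    rm_mask <- borderline_undersample(X, y, m = m, seed = derive_seed(seed, 1L),
                                      n_remove = cap)
    n_removed <- sum(rm_mask)
    out_X <- X[!rm_mask, , drop = FALSE]
    out_y <- y[!rm_mask]
  }
  n_maj2 <- sum(out_y != mc)
  n_min2 <- sum(out_y == mc)
  need <- max(0, ceiling(n_maj2 / target_ir) - n_min2)
  n_syn <- 0L
  if (need > 0 && imbalance_ratio(out_y) > target_ir * 1.05) {
    syn <- borderline_smote(out_X, out_y, m = m, k = k, n_new = need,
                            seed = derive_seed(seed, 2L))
    n_syn <- nrow(syn)
    if (n_syn > 0) {
      out_X <- rbind(out_X, syn)
      out_y <- c(out_y, rep(mc, n_syn))
    }
  }
  structure(list(X_out = out_X, y_out = out_y,
                 n_synthetic = n_syn, n_removed = n_removed,
                 ir_before = ir_before, ir_after = imbalance_ratio(out_y),
                 synthetic_rows = if (n_syn > 0)
                   seq(nrow(out_X) - n_syn + 1, nrow(out_X)) else integer(0)),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat(sprintf(
    "Hybrid balance: IR %.2f -> %.2f (%d majority removed, %d synthetic added)\n",
    x$ir_before, x$ir_after, x$n_removed, x$n_synthetic))
  invisible(x)
}
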