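#' Matthews correlation coefficient
#'
#' MCC for binary labels, computed from the confusion matrix as
#' \deqn{(TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' A zero denominator (e.g. an all-one-class prediction) returns 0 by
#' convention.
#'
#' @param y_true,y_pred binary 0/1 vectors of equal length.
#' @return a scalar in \[-1, 1\].
#' @export
mcc <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Geometric mean of sensitivity and specificity
#'
#' @inheritParams mcc
#' @return sqrt(sensitivity * specificity); a group absent from `y_true`
#'   contributes rate 0.
#' @export
g_mean <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  sens <- if (any(y_true == 1)) mean(y_pred[y_true == 1] == 1) else 0
  spec <- if (any(y_true == 0)) mean(y_pred[y_true == 0] == 0) else 0
  sqrt(sens * spec)
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic; ties receive
#' midranks.
#'
#' @param y_true binary 0/1 vector.
#' @param scores real-valued scores, higher meaning more class-1-like.
#' @return a scalar in \[0, 1\].
#' @export
auc_rank <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("auc_rank: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

classification_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(mcc = mcc(y_true, y_pred),
    accuracy = mean(y_true == y_pred),
    precision = prec,
    f1 = f1,
    g_mean = g_mean(y_true, y_pred),
    auc = if (is.null(scores)) NA_real_ else auc_rank(y_true, scores))
}

#' Seeded stratified cross-validation folds
#'
#' Partitions samples into `n_folds` folds preserving class proportions to
#' within one sample per fold.
#'
#' @param labels binary 0/1 vector.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed controlling the shuffle.
#' @return an object of class `fold_plan`: list with `n_folds`, `seed`,
#'   `folds` (per-fold list of `train`/`test` index vectors) and
#'   `assignment` (fold id per sample).
#' @export
stratified_folds <- function(labels, n_folds = 5, seed = 1) {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < n_folds)) {
    stop(sprintf(
      "stratified_folds: smallest class has %d samples < %d folds; use fewer folds",
      min(tab), n_folds))
  }
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      assignment[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds <- lapply(seq_len(n_folds), function(f) {
    list(train = which(assignment != f), test = which(assignment == f))
  })
  structure(list(n_folds = n_folds, seed = seed, folds = folds,
                 assignment = assignment),
            class = "fold_plan")
}

# Assemble a metrics_report from a per-fold metrics matrix (rows = folds).
metrics_report <- function(per_fold, fold_plan, config = list()) {
  per_fold <- as.data.frame(per_fold)
  agg <- colMeans(per_fold, na.rm = TRUE)
  structure(list(per_fold = per_fold, aggregate = agg,
                 fold_plan = fold_plan, config = config,
                 seed = fold_plan$seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Cross-validated metrics (%d folds, seed %s)\n",
              x$fold_plan$n_folds, x$seed))
  print(round(x$aggregate, 4))
  invisible(x)
}
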