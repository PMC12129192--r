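# ---- base learner registry -------------------------------------------------
# Every learner exposes fit(X, y, seed) -> model and a class-1 probability
# predictor; probabilities are clamped away from {0,1} so log-loss stays finite.

clamp_prob <- function(p) {
  p[!is.finite(p)] <- 0.5
  pmin(pmax(p, 1e-6), 1 - 1e-6)
}

#' Available base classifiers
#'
#' The five model-based learners (KNN, logistic regression, naive Bayes,
#' RBF SVM, random forest) plus the extra members of the concatenation set
#' (decision tree, gradient boosting, multilayer perceptron).
#'
#' @return character vector of learner names.
#' @export
available_learners <- function() {
  c("knn", "lr", "nb", "svm", "rf", "tree", "gboost", "mlp")
}

fit_learner <- function(name, X, y, seed = 1) {
  X <- as.matrix(X); y <- as.integer(y)
  model <- switch(
    name,
    knn = list(X = X, y = y, k = 5),
    lr = suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial())),
    nb = e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0, 1))),
    svm = suppressWarnings(                 # constant columns trip scaling
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                 probability = TRUE)),
    rf = ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                        probability = TRUE, num.trees = 300, seed = seed,
                        num.threads = 1),
    tree = rpart::rpart(y ~ ., data = data.frame(y = factor(y), X),
                        method = "class"),
    gboost = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("learner 'gboost' requires the xgboost package")
      xgboost::xgboost(x = X, y = factor(y, levels = c(0, 1)), nrounds = 50,
                       max_depth = 3, learning_rate = 0.3, nthreads = 1,
                       verbosity = 0)
    },
    mlp = with_seed(seed, nnet::nnet(x = X, y = y, size = 5, decay = 0.01,
                                     maxit = 200, trace = FALSE,
                                     entropy = TRUE)),
    stop(sprintf("unknown learner '%s'", name)))
  structure(list(name = name, model = model, p_features = ncol(X)),
            class = "base_learner")
}

predict_proba <- function(fit, X) {
  X <- as.matrix(X)
  m <- fit$model
  p <- switch(
    fit$name,
    knn = {
      pr <- class::knn(m$X, X, factor(m$y, levels = c(0, 1)), k = m$k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    lr = as.numeric(stats::plogis(cbind(1, X) %*% m$coefficients)),
    nb = stats::predict(m, as.data.frame(X), type = "raw")[, "1"],
    svm = {
      pr <- stats::predict(m, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = stats::predict(m, as.data.frame(X), num.threads = 1)$predictions[, "1"],
    tree = stats::predict(m, data.frame(X), type = "prob")[, "1"],
    gboost = stats::predict(m, X, type = "response"),
    mlp = as.numeric(stats::predict(m, X, type = "raw")))
  clamp_prob(as.numeric(p))
}

log_loss <- function(y, p) {
  p <- clamp_prob(p)
  -mean(ifelse(y == 1, log(p), log(1 - p)))
}

# label from a class-1 probability; ties at 0.5 go to class 0 (documented)
prob_to_label <- function(p) as.integer(p > 0.5)

# ---- integration strategies ------------------------------------------------

check_blocks <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1) stop("omics blocks must be row-aligned")
  if (any(vapply(blocks, anyNA, logical(1))))
    stop("omics blocks must be complete (impute upstream)")
  invisible(n)
}

cv_classify <- function(make_features, y, classifier, plan, seed) {
  per_fold <- matrix(NA_real_, plan$n_folds, 6)
  colnames(per_fold) <- c("mcc", "accuracy", "precision", "f1", "g_mean", "auc")
  failed <- 0L
  for (f in seq_len(plan$n_folds)) {
    tr <- plan$folds[[f]]$train; te <- plan$folds[[f]]$test
    res <- tryCatch(with_seed(derive_seed(seed, f), {
      feat <- make_features(tr, te)
      fit <- fit_learner(classifier, feat$train, y[tr],
                         seed = derive_seed(seed, f))
      p <- predict_proba(fit, feat$test)
      classification_metrics(y[te], prob_to_label(p), p)
    }), error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else per_fold[f, ] <- res
  }
  if (failed > 0)
    warning(sprintf("%s: %d/%d folds failed; aggregating the rest",
                    classifier, failed, plan$n_folds))
  metrics_report(per_fold[stats::complete.cases(per_fold), , drop = FALSE],
                 plan, config = list(classifier = classifier))
}

#' Concatenation-based multi-omics integration
#'
#' Column-concatenates the selected blocks (z-scored with training-fold
#' statistics only) and cross-validates each classifier in the set.
#'
#' @param blocks named list of row-aligned samples x features matrices.
#' @param y binary 0/1 labels.
#' @param classifiers learner names (default: all eight of
#'   [available_learners()]).
#' @param n_folds stratified folds (default 5).
#' @param seed fold and learner seed.
#' @return named list of `metrics_report`, one per classifier.
#' @export
concat_integrate <- function(blocks, y, classifiers = available_learners(),
                             n_folds = 5, seed = 1) {
  check_blocks(blocks)
  Xall <- do.call(cbind, lapply(blocks, as.matrix))
  plan <- stratified_folds(y, n_folds, seed)
  make_features <- function(tr, te) {
    ctr <- colMeans(Xall[tr, , drop = FALSE])
    scl <- apply(Xall[tr, , drop = FALSE], 2, stats::sd)
    list(train = zscore_cols(Xall[tr, , drop = FALSE], ctr, scl),
         test = zscore_cols(Xall[te, , drop = FALSE], ctr, scl))
  }
  out <- lapply(classifiers, function(cl)
    cv_classify(make_features, y, cl, plan, seed))
  names(out) <- classifiers
  out
}

#' Transformation-based multi-omics integration
#'
#' Reduces each block to its target dimensionality with a principal-component
#' projection fitted on the training folds only, concatenates the projected
#' blocks, and cross-validates each classifier.
#'
#' @inheritParams concat_integrate
#' @param reduced_dims per-block target dimensions (recycled / clamped to
#'   block widths with a warning).
#' @return named list of `metrics_report`, one per classifier.
#' @export
transform_integrate <- function(blocks, y, reduced_dims = c(3, 4, 5),
                                classifiers = available_learners(),
                                n_folds = 5, seed = 1) {
  check_blocks(blocks)
  dims <- rep_len(reduced_dims, length(blocks))
  widths <- vapply(blocks, ncol, integer(1))
  if (any(dims > widths)) {
    warning("transform_integrate: target dims clamped to block widths")
    dims <- pmin(dims, widths)
  }
  plan <- stratified_folds(y, n_folds, seed)
  make_features <- function(tr, te) {
    proj <- lapply(seq_along(blocks), function(b) {
      Xb <- as.matrix(blocks[[b]])
      ctr <- colMeans(Xb[tr, , drop = FALSE])
      scl <- apply(Xb[tr, , drop = FALSE], 2, stats::sd)
      Ztr <- zscore_cols(Xb[tr, , drop = FALSE], ctr, scl)
      Zte <- zscore_cols(Xb[te, , drop = FALSE], ctr, scl)
      d <- dims[b]
      rot <- svd(Ztr, nu = 0, nv = d)$v
      list(train = Ztr %*% rot, test = Zte %*% rot)
    })
    list(train = do.call(cbind, lapply(proj, `[[`, "train")),
         test = do.call(cbind, lapply(proj, `[[`, "test")))
  }
  out <- lapply(classifiers, function(cl)
    cv_classify(make_features, y, cl, plan, seed))
  names(out) <- classifiers
  out
}

#' Model-based soft-voting integration
#'
#' For each omics block, selects (by inner-CV negative log-loss on the
#' training folds) the best of the five base learners, fits it on the
#' training folds, and averages the per-block class-probability vectors into
#' an unweighted soft vote. Ties at probability 0.5 resolve to class 0.
#'
#' @inheritParams concat_integrate
#' @param base_learners candidate learner names (default the five
#'   model-based learners: knn, lr, nb, svm, rf).
#' @param inner_folds folds of the learner-selection CV (default 3).
#' @return a `metrics_report` with `config$selected` recording the learner
#'   chosen per block per fold.
#' @export
model_based_integrate <- function(blocks, y,
                                  base_learners = c("knn", "lr", "nb",
                                                    "svm", "rf"),
                                  n_folds = 5, inner_folds = 3, seed = 1) {
  check_blocks(blocks)
  plan <- stratified_folds(y, n_folds, seed)
  per_fold <- matrix(NA_real_, plan$n_folds, 6)
  colnames(per_fold) <- c("mcc", "accuracy", "precision", "f1", "g_mean", "auc")
  selected <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    tr <- plan$folds[[f]]$train; te <- plan$folds[[f]]$test
    votes <- matrix(0, length(te), length(blocks))
    sel_f <- character(length(blocks))
    for (b in seq_along(blocks)) {
      Xb <- as.matrix(blocks[[b]])
      ctr <- colMeans(Xb[tr, , drop = FALSE])
      scl <- apply(Xb[tr, , drop = FALSE], 2, stats::sd)
      Ztr <- zscore_cols(Xb[tr, , drop = FALSE], ctr, scl)
      Zte <- zscore_cols(Xb[te, , drop = FALSE], ctr, scl)
      inner <- stratified_folds(y[tr], inner_folds,
                                derive_seed(seed, f * 10L + b))
      losses <- vapply(base_learners, function(cl) {
        ll <- vapply(seq_along(inner$folds), function(fi) {
          fd <- inner$folds[[fi]]
          tryCatch(with_seed(derive_seed(seed, f * 1000L + b * 10L + fi), {
            fit <- fit_learner(cl, Ztr[fd$train, , drop = FALSE],
                               y[tr][fd$train], seed = derive_seed(seed, b))
            log_loss(y[tr][fd$test],
                     predict_proba(fit, Ztr[fd$test, , drop = FALSE]))
          }), error = function(e) Inf)
        }, numeric(1))
        mean(ll)
      }, numeric(1))
      best <- base_learners[which.min(losses)]
      sel_f[b] <- best
      votes[, b] <- with_seed(derive_seed(seed, f * 100L + b), {
        fit <- fit_learner(best, Ztr, y[tr], seed = derive_seed(seed, f))
        predict_proba(fit, Zte)
      })
    }
    selected[[f]] <- stats::setNames(sel_f, names(blocks))
    p_vote <- rowMeans(votes)
    per_fold[f, ] <- classification_metrics(y[te], prob_to_label(p_vote), p_vote)
  }
  metrics_report(per_fold, plan,
                 config = list(strategy = "model_based", selected = selected))
}

#' Block-ladder comparison across integration strategies
#'
#' Runs the 3 x 3 grid of integration strategy (concatenation,
#' transformation, model-based) against the cumulative block ladder
#' C (clinical BDI), C+P (+ polygenic score), C+P+M (+ methylation markers).
#' For concatenation and transformation the best classifier by aggregate MCC
#' represents the strategy; model-based reports its soft vote.
#'
#' @param blocks named list with elements `clinical_bdi`, `prs`,
#'   `methylation_top`.
#' @param y binary 0/1 labels.
#' @param classifiers learner set for concat/transform (default all eight).
#' @param n_folds,seed cross-validation controls.
#' @return data.frame with one row per (strategy, ladder) cell and metric
#'   columns; full reports in `attr(, "reports")`.
#' @export
strategy_ladder <- function(blocks, y, classifiers = available_learners(),
                            n_folds = 5, seed = 1) {
  stopifnot(all(c("clinical_bdi", "prs", "methylation_top") %in% names(blocks)))
  ladders <- list(C = c("clinical_bdi"),
                  CP = c("clinical_bdi", "prs"),
                  CPM = c("clinical_bdi", "prs", "methylation_top"))
  reports <- list()
  rows <- list()
  for (lad in names(ladders)) {
    bl <- blocks[ladders[[lad]]]
    cc <- concat_integrate(bl, y, classifiers, n_folds, seed)
    tf <- transform_integrate(bl, y, classifiers = classifiers,
                              n_folds = n_folds, seed = seed)
    mb <- model_based_integrate(bl, y, n_folds = n_folds, seed = seed)
    best_of <- function(reps) reps[[which.max(vapply(
      reps, function(r) r$aggregate[["mcc"]], numeric(1)))]]
    cells <- list(concat = best_of(cc), transform = best_of(tf), model = mb)
    for (s in names(cells)) {
      reports[[paste(s, lad, sep = ".")]] <- cells[[s]]
      rows[[paste(s, lad, sep = ".")]] <-
        data.frame(strategy = s, ladder = lad,
                   t(cells[[s]]$aggregate), row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
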