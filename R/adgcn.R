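# Patient-similarity graph construction and the AD-GCN network
# (graph-convolution + GraphSAGE hidden layers, widths 8 and 3).

#' Cosine composite similarity of multi-omics feature rows
#'
#' @param features samples x features matrix, z-scored per column.
#' @return symmetric samples x samples similarity in \[-1, 1\], diagonal 1;
#'   zero-norm rows get similarity 0 everywhere off-diagonal (with a warning).
#' @export
composite_similarity <- function(features) {
  X <- as.matrix(features)
  stopifnot(nrow(X) >= 2)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    warning(sprintf("composite_similarity: %d zero-norm rows; similarities set to 0",
                    sum(zero)))
    nrm[zero] <- 1
  }
  Xn <- X / nrm
  S <- Xn %*% t(Xn)
  S[zero, ] <- 0; S[, zero] <- 0
  diag(S) <- 1
  S
}

#' Similarity-thresholded edge set
#'
#' Unordered pairs with similarity strictly greater than the threshold.
#'
#' @param similarity symmetric similarity matrix.
#' @param sim_threshold retention cut (default 0.5, strict `>`).
#' @return two-column matrix of node pairs (i < j); zero rows allowed.
#' @export
threshold_edges <- function(similarity, sim_threshold = 0.5) {
  idx <- which(upper.tri(similarity) & similarity > sim_threshold,
               arr.ind = TRUE)
  unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE])
}

#' K-nearest-neighbour edge expansion
#'
#' Adds an edge from every node to each of its `k` nearest neighbours
#' (Euclidean on the feature rows), symmetrizes, and unions with an existing
#' edge set.
#'
#' @param features samples x features matrix (z-scored upstream).
#' @param k neighbour count (`< n`).
#' @param existing_edges two-column pair matrix (may have zero rows).
#' @return deduplicated two-column pair matrix (i < j).
#' @export
knn_expand <- function(features, k, existing_edges = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  stopifnot(k < n, k >= 1)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  new_pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ], seq_len(n))[seq_len(k)]
    cbind(pmin(i, nb), pmax(i, nb))
  }))
  pairs <- rbind(existing_edges, new_pairs)
  pairs <- unique(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
  unname(pairs)
}

#' Cognitive-score edge weights
#'
#' Edge weight = Pearson correlation of the two endpoint samples' 12
#' cognitive scores, floored at `eps` so the graph stays nonnegatively
#' weighted (anti-correlated pairs keep a vanishing link rather than a
#' negative one).
#'
#' @param cognitive samples x 12 cognitive-score matrix.
#' @param edges two-column pair matrix.
#' @param eps weight floor (default 1e-3).
#' @return per-edge weight vector in (0, 1\].
#' @export
cognitive_edge_weights <- function(cognitive, edges, eps = 1e-3) {
  C <- as.matrix(cognitive)
  if (nrow(edges) == 0) return(numeric(0))
  sds <- apply(C, 1, stats::sd)
  if (any(sds < 1e-12))
    warning("cognitive_edge_weights: zero-variance cognitive vectors; their edges get the floor weight")
  w <- vapply(seq_len(nrow(edges)), function(e) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (sds[i] < 1e-12 || sds[j] < 1e-12) return(eps)
    max(stats::cor(C[i, ], C[j, ]), eps)
  }, numeric(1))
  w
}

#' Build a patient-similarity graph
#'
#' The three ablation strategies:
#' `sim_only_w` (1) — similarity-thresholded edges with cognitive-correlation
#' weights; `sim_knn_unweighted` (2) — thresholded + kNN-expanded edges, all
#' weights 1; `sim_knn_w` (3, the full model) — thresholded + kNN-expanded
#' edges with cognitive weights.
#'
#' @param features samples x features matrix (z-scored internally).
#' @param cognitive samples x 12 cognitive scores.
#' @param strategy `"sim_only_w"`, `"sim_knn_unweighted"`, `"sim_knn_w"`, or
#'   1/2/3.
#' @param sim_threshold similarity cut (default 0.5).
#' @param k kNN expansion neighbours (default 10).
#' @param neutral_nodes optional node indices whose incident edges get
#'   weight 1 regardless of cognitive correlation (strict evaluation mode,
#'   which withholds test patients' cognitive scores from the graph).
#' @return an object of class `graph_spec`: `n_nodes`, `edges`, `weights`,
#'   `strategy`, `sim_threshold`, `k`.
#' @export
build_graph <- function(features, cognitive, strategy = "sim_knn_w",
                        sim_threshold = 0.5, k = 10, neutral_nodes = NULL) {
  if (is.numeric(strategy))
    strategy <- c("sim_only_w", "sim_knn_unweighted", "sim_knn_w")[strategy]
  strategy <- match.arg(strategy,
                        c("sim_only_w", "sim_knn_unweighted", "sim_knn_w"))
  Z <- zscore_cols(features)
  S <- composite_similarity(Z)
  edges <- threshold_edges(S, sim_threshold)
  if (strategy != "sim_only_w") edges <- knn_expand(Z, k, edges)
  weights <- if (strategy == "sim_knn_unweighted") {
    rep(1, nrow(edges))
  } else {
    cognitive_edge_weights(cognitive, edges)
  }
  if (!is.null(neutral_nodes) && nrow(edges) > 0) {
    touched <- edges[, 1] %in% neutral_nodes | edges[, 2] %in% neutral_nodes
    weights[touched] <- 1
  }
  structure(list(n_nodes = nrow(as.matrix(features)), edges = edges,
                 weights = weights, strategy = strategy,
                 sim_threshold = sim_threshold,
                 k = if (strategy == "sim_only_w") NA_integer_ else k),
            class = "graph_spec")
}

#' @export
print.graph_spec <- function(x, ...) {
  cat(sprintf("Patient-similarity graph (%s): %d nodes, %d edges, mean weight %.3f\n",
              x$strategy, x$n_nodes, nrow(x$edges),
              if (length(x$weights)) mean(x$weights) else NA_real_))
  invisible(x)
}

graph_adjacency <- function(graph) {
  A <- matrix(0, graph$n_nodes, graph$n_nodes)
  if (nrow(graph$edges) > 0) {
    A[graph$edges] <- graph$weights
    A[graph$edges[, c(2, 1), drop = FALSE]] <- graph$weights
  }
  A
}

#' Symmetrically normalized adjacency operator
#'
#' `A_hat = D^(-1/2) (A + I) D^(-1/2)` with unit self-loops, the standard
#' graph-convolution propagation operator; isolated nodes reduce to the
#' identity row.
#'
#' @param graph a [build_graph()] result.
#' @return dense n x n operator with spectral radius at most 1.
#' @export
normalize_adjacency <- function(graph) {
  A <- graph_adjacency(graph) + diag(graph$n_nodes)
  d <- rowSums(A)
  Dm <- 1 / sqrt(d)
  A * outer(Dm, Dm)
}

# Row-normalized neighbour-mean operator (self excluded; isolated -> zero row)
neighbor_mean_operator <- function(graph) {
  A <- graph_adjacency(graph)
  d <- rowSums(A)
  d[d < 1e-12] <- Inf
  A / d
}

# ---- network ---------------------------------------------------------------

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize AD-GCN parameters
#'
#' Glorot-uniform kernels for the graph-convolution layer (input -> 8), the
#' GraphSAGE layer (8 -> 3, separate self and neighbour kernels) and the
#' output head (3 -> 2), plus batch-norm state per hidden layer.
#'
#' @param input_dim node feature dimension.
#' @param hidden hidden widths (default `c(8, 3)`).
#' @param seed RNG seed.
#' @return an `adgcn_params` list.
#' @export
adgcn_init <- function(input_dim, hidden = c(8, 3), seed = 1) {
  h1 <- hidden[1]; h2 <- hidden[2]
  with_seed(seed, {
    structure(list(
      W1 = glorot(input_dim, h1), b1 = numeric(h1),
      g1 = rep(1, h1), be1 = numeric(h1),
      W2s = glorot(h1, h2), W2n = glorot(h1, h2), b2 = numeric(h2),
      g2 = rep(1, h2), be2 = numeric(h2),
      Wout = glorot(h2, 2), bout = numeric(2),
      rm1 = numeric(h1), rv1 = rep(1, h1),
      rm2 = numeric(h2), rv2 = rep(1, h2),
      hidden = hidden), class = "adgcn_params")
  })
}

bn_eps <- 1e-5

bn_forward <- function(Xin, gamma, beta, mode, rmean, rvar, momentum = 0.1) {
  n <- nrow(Xin)
  if (mode == "train") {
    mu <- colMeans(Xin)
    v <- colMeans(sweep(Xin, 2, mu)^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- rmean; v <- rvar
  }
  inv_std <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(sweep(Xin, 2, mu), 2, inv_std, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, inv_std = inv_std, rmean = rmean, rvar = rvar)
}

bn_backward <- function(dY, xhat, inv_std, gamma) {
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*")
  dX <- sweep(dX, 2, inv_std, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

#' AD-GCN forward pass
#'
#' `H1 = BN(ReLU(A_hat X W1 + b1))` (graph convolution, width 8);
#' `H2 = BN(ReLU(H1 W2s + meanN(H1) W2n + b2))` (GraphSAGE, width 3, with
#' `meanN` the weighted neighbour mean, self excluded, zero for isolated
#' nodes); class scores `H2 Wout + bout`. Batch statistics in train mode,
#' running statistics in eval mode.
#'
#' @param Ahat normalized adjacency from [normalize_adjacency()].
#' @param M neighbour-mean operator from the same graph.
#' @param X node feature matrix.
#' @param params an [adgcn_init()] state.
#' @param mode `"train"` or `"eval"`.
#' @return list with `scores`, `probs`, hidden embeddings and (train mode)
#'   the backprop cache and updated running statistics.
#' @export
adgcn_forward <- function(Ahat, M, X, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  p <- params
  AX <- Ahat %*% X
  Z1 <- sweep(AX %*% p$W1, 2, p$b1, "+")
  R1 <- pmax(Z1, 0)
  bn1 <- bn_forward(R1, p$g1, p$be1, mode, p$rm1, p$rv1)
  H1 <- bn1$y
  N1 <- M %*% H1
  Z2 <- sweep(H1 %*% p$W2s + N1 %*% p$W2n, 2, p$b2, "+")
  R2 <- pmax(Z2, 0)
  bn2 <- bn_forward(R2, p$g2, p$be2, mode, p$rm2, p$rv2)
  H2 <- bn2$y
  scores <- sweep(H2 %*% p$Wout, 2, p$bout, "+")
  if (any(!is.finite(scores)))
    stop("adgcn_forward: non-finite activation in output layer")
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  probs <- e / rowSums(e)
  list(scores = scores, probs = probs, H1 = H1, H2 = H2,
       cache = list(AX = AX, Z1 = Z1, R1 = R1, bn1 = bn1, N1 = N1,
                    Z2 = Z2, R2 = R2, bn2 = bn2),
       rm1 = bn1$rmean, rv1 = bn1$rvar, rm2 = bn2$rmean, rv2 = bn2$rvar)
}

adgcn_backward <- function(fw, M, y, train_mask, params) {
  p <- params; ca <- fw$cache
  n_tr <- length(train_mask)
  dS <- matrix(0, nrow(fw$probs), 2)
  Y1 <- cbind(y == 0, y == 1)[train_mask, , drop = FALSE]
  dS[train_mask, ] <- (fw$probs[train_mask, , drop = FALSE] - Y1) / n_tr
  dWout <- crossprod(fw$H2, dS); dbout <- colSums(dS)
  dH2 <- dS %*% t(p$Wout)
  b2g <- bn_backward(dH2, ca$bn2$xhat, ca$bn2$inv_std, p$g2)
  dZ2 <- b2g$dX * (ca$Z2 > 0)
  dW2s <- crossprod(fw$H1, dZ2); dW2n <- crossprod(ca$N1, dZ2)
  db2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(p$W2s) + crossprod(M, dZ2 %*% t(p$W2n))
  b1g <- bn_backward(dH1, ca$bn1$xhat, ca$bn1$inv_std, p$g1)
  dZ1 <- b1g$dX * (ca$Z1 > 0)
  dW1 <- crossprod(ca$AX, dZ1); db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, g1 = b1g$dgamma, be1 = b1g$dbeta,
       W2s = dW2s, W2n = dW2n, b2 = db2, g2 = b2g$dgamma, be2 = b2g$dbeta,
       Wout = dWout, bout = dbout)
}

#' AD-GCN training configuration
#'
#' @param epochs maximum epochs (default 300).
#' @param learning_rate Adam step size (default 0.01).
#' @param weight_decay L2 penalty added to kernel gradients (default 5e-4).
#' @param grad_clip_norm global gradient-norm clip (default 1.0).
#' @param seed initialization seed.
#' @param early_stop_patience epochs without training-loss improvement
#'   before stopping (default 50).
#' @param hidden hidden widths (default `c(8, 3)`).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 300, learning_rate = 0.01,
                         weight_decay = 5e-4, grad_clip_norm = 1.0,
                         seed = 1, early_stop_patience = 50,
                         hidden = c(8, 3)) {
  stopifnot(epochs > 0, learning_rate > 0, grad_clip_norm > 0,
            early_stop_patience > 0)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 weight_decay = weight_decay, grad_clip_norm = grad_clip_norm,
                 seed = seed, early_stop_patience = early_stop_patience,
                 hidden = hidden), class = "train_config")
}

trainable <- c("W1", "b1", "g1", "be1", "W2s", "W2n", "b2", "g2", "be2",
               "Wout", "bout")
decayed <- c("W1", "W2s", "W2n", "Wout")

#' Train the AD-GCN network (transductive)
#'
#' Full-batch Adam minimization of softmax cross-entropy over the training
#' nodes; all nodes propagate, only masked nodes contribute loss. Gradients
#' are clipped at a global norm; training stops on loss plateau.
#'
#' @param graph a [build_graph()] result.
#' @param X node feature matrix (z-scored upstream).
#' @param y binary 0/1 node labels.
#' @param train_mask indices of training nodes (both classes present).
#' @param config a [train_config()].
#' @return list with trained `params` and per-epoch `history`.
#' @export
adgcn_train <- function(graph, X, y, train_mask, config = train_config()) {
  stopifnot(length(train_mask) > 0, length(unique(y[train_mask])) == 2)
  X <- as.matrix(X)
  Ahat <- normalize_adjacency(graph)
  M <- neighbor_mean_operator(graph)
  params <- adgcn_init(ncol(X), config$hidden, seed = config$seed)
  mstate <- vstate <- lapply(params[trainable], function(x) x * 0)
  history <- numeric(0)
  best <- Inf; wait <- 0
  for (ep in seq_len(config$epochs)) {
    fw <- adgcn_forward(Ahat, M, X, params, mode = "train")
    params$rm1 <- fw$rm1; params$rv1 <- fw$rv1
    params$rm2 <- fw$rm2; params$rv2 <- fw$rv2
    pr <- fw$probs[cbind(train_mask, y[train_mask] + 1L)]
    loss <- -mean(log(pmax(pr, 1e-12)))
    if (!is.finite(loss))
      stop(sprintf("adgcn_train: loss diverged at epoch %d (last finite epoch %d)",
                   ep, length(history)))
    history <- c(history, loss)
    gr <- adgcn_backward(fw, M, y, train_mask, params)
    for (nm in decayed) gr[[nm]] <- gr[[nm]] + config$weight_decay * params[[nm]]
    gnorm <- sqrt(sum(vapply(gr, function(g) sum(g^2), numeric(1))))
    if (gnorm > config$grad_clip_norm) {
      gr <- lapply(gr, function(g) g * config$grad_clip_norm / gnorm)
    }
    for (nm in trainable) {
      mstate[[nm]] <- 0.9 * mstate[[nm]] + 0.1 * gr[[nm]]
      vstate[[nm]] <- 0.999 * vstate[[nm]] + 0.001 * gr[[nm]]^2
      mhat <- mstate[[nm]] / (1 - 0.9^ep)
      vhat <- vstate[[nm]] / (1 - 0.999^ep)
      params[[nm]] <- params[[nm]] -
        config$learning_rate * mhat / (sqrt(vhat) + 1e-8)
    }
    if (loss < best - 1e-4) { best <- loss; wait <- 0 } else wait <- wait + 1
    if (wait >= config$early_stop_patience) break
  }
  list(params = params, history = history, Ahat = Ahat, M = M)
}

# ---- S3 model interface ----------------------------------------------------

#' Fit the AD-GCN patient-similarity graph classifier
#'
#' Builds the patient-similarity graph over all samples from the
#' concatenated multi-omics features and cognitive scores, then trains the
#' two-hidden-layer graph network (graph-convolution width 8, GraphSAGE
#' width 3) transductively: every node propagates, only `train_idx` nodes
#' contribute to the loss.
#'
#' @param features samples x features multi-omics matrix (z-scored
#'   internally).
#' @param cognitive samples x 12 cognitive-score matrix (edge-weight signal).
#' @param labels binary 0/1 node labels.
#' @param train_idx training node indices (default: all nodes).
#' @param strategy graph strategy, see [build_graph()] (default the full
#'   model `"sim_knn_w"`).
#' @param sim_threshold,k graph-construction controls.
#' @param config a [train_config()].
#' @param neutral_nodes see [build_graph()] (strict evaluation mode).
#' @return an object of class `adgcn`, with methods `print`, `summary`,
#'   `predict`, `plot` and `fitted`.
#' @examples
#' co <- generate_cohort(cohort_config(n_samples = 60, n_snps = 40,
#'                                     n_ld_blocks = 8, n_probes = 60,
#'                                     n_informative_probes = 4, seed = 1))
#' X <- cbind(co$cognitive[, 1:2], co$methylation[, co$truth$informative_probes])
#' fit <- adgcn_fit(X, co$cognitive, co$labels,
#'                  config = train_config(epochs = 30, seed = 1))
#' print(fit)
#' table(predict(fit, type = "class"), co$labels)
#' @export
adgcn_fit <- function(features, cognitive, labels, train_idx = NULL,
                      strategy = "sim_knn_w", sim_threshold = 0.5, k = 10,
                      config = train_config(), neutral_nodes = NULL) {
  X <- zscore_cols(features)
  labels <- as.integer(labels)
  if (is.null(train_idx)) train_idx <- seq_along(labels)
  graph <- build_graph(features, cognitive, strategy, sim_threshold, k,
                       neutral_nodes = neutral_nodes)
  tr <- adgcn_train(graph, X, labels, train_idx, config)
  fw <- adgcn_forward(tr$Ahat, tr$M, X, tr$params, mode = "eval")
  structure(list(params = tr$params, graph = graph, history = tr$history,
                 Ahat = tr$Ahat, M = tr$M, X = X, labels = labels,
                 train_idx = train_idx, config = config,
                 probs = fw$probs, call = match.call()),
            class = "adgcn")
}

#' @export
print.adgcn <- function(x, ...) {
  cat("AD-GCN patient-similarity graph classifier\n")
  cat(sprintf("  graph: %s, %d nodes, %d edges (threshold %.2f%s)\n",
              x$graph$strategy, x$graph$n_nodes, nrow(x$graph$edges),
              x$graph$sim_threshold,
              if (is.na(x$graph$k)) "" else sprintf(", k = %d", x$graph$k)))
  cat(sprintf("  layers: %d -> %d (GCN) -> %d (GraphSAGE) -> 2\n",
              ncol(x$X), x$params$hidden[1], x$params$hidden[2]))
  cat(sprintf("  trained %d epochs, final loss %.4f; %d/%d nodes in training mask\n",
              length(x$history), utils::tail(x$history, 1),
              length(x$train_idx), length(x$labels)))
  invisible(x)
}

#' @export
summary.adgcn <- function(object, ...) {
  pred <- prob_to_label(object$probs[, 2])
  tr <- object$train_idx
  te <- setdiff(seq_along(object$labels), tr)
  out <- list(
    train = classification_metrics(object$labels[tr], pred[tr],
                                   object$probs[tr, 2]),
    test = if (length(te) >= 2 && length(unique(object$labels[te])) == 2)
      classification_metrics(object$labels[te], pred[te], object$probs[te, 2])
    else NULL,
    graph = object$graph, history = object$history)
  class(out) <- "summary.adgcn"
  out
}

#' @export
print.summary.adgcn <- function(x, ...) {
  print(x$graph)
  cat("Training-node metrics:\n"); print(round(x$train, 4))
  if (!is.null(x$test)) { cat("Held-out-node metrics:\n"); print(round(x$test, 4)) }
  invisible(x)
}

#' Predict node classes or probabilities from a fitted AD-GCN
#'
#' Transductive model: predictions are for the nodes of the fitted graph
#' (evaluation-mode forward pass with running batch-norm statistics).
#'
#' @param object an [adgcn_fit()] result.
#' @param type `"prob"` (class-1 probability) or `"class"`.
#' @param nodes node indices (default all).
#' @param ... unused.
#' @export
predict.adgcn <- function(object, type = c("prob", "class"), nodes = NULL,
                          ...) {
  type <- match.arg(type)
  p <- object$probs[, 2]
  if (!is.null(nodes)) p <- p[nodes]
  if (type == "prob") p else prob_to_label(p)
}

#' @export
fitted.adgcn <- function(object, ...) object$probs[, 2]

#' Plot the AD-GCN training-loss history
#'
#' @param x an `adgcn` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.adgcn <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training cross-entropy",
                 main = "AD-GCN training loss", ...)
  invisible(x)
}

#' Transductive cross-validation of the AD-GCN
#'
#' Stratified folds over nodes; the graph is built once on all nodes (the
#' transductive design), each fold trains on its training mask and is scored
#' on its test mask. `strict = TRUE` rebuilds the graph per fold with the
#' test nodes' cognitive edge weights neutralized to 1.
#'
#' @inheritParams adgcn_fit
#' @param n_folds folds (default 5).
#' @param seed fold seed.
#' @param strict withhold test-node cognitive weights (default FALSE).
#' @param fold_plan optional pre-built [stratified_folds()] plan (shared
#'   folds across ablation strategies).
#' @return a `metrics_report` whose config records strategy, k, threshold
#'   and seed.
#' @export
cross_validate_adgcn <- function(features, cognitive, labels,
                                 strategy = "sim_knn_w", config = train_config(),
                                 n_folds = 5, seed = 1, sim_threshold = 0.5,
                                 k = 10, strict = FALSE, fold_plan = NULL) {
  labels <- as.integer(labels)
  X <- zscore_cols(features)
  plan <- fold_plan %||% stratified_folds(labels, n_folds, seed)
  base_graph <- build_graph(features, cognitive, strategy, sim_threshold, k)
  per_fold <- matrix(NA_real_, plan$n_folds, 6)
  colnames(per_fold) <- c("mcc", "accuracy", "precision", "f1", "g_mean", "auc")
  for (f in seq_len(plan$n_folds)) {
    te <- plan$folds[[f]]$test
    graph <- if (strict && strategy != "sim_knn_unweighted") {
      build_graph(features, cognitive, strategy, sim_threshold, k,
                  neutral_nodes = te)
    } else base_graph
    cfg <- config; cfg$seed <- derive_seed(config$seed, f)
    tr_res <- adgcn_train(graph, X, labels, plan$folds[[f]]$train, cfg)
    fw <- adgcn_forward(tr_res$Ahat, tr_res$M, X, tr_res$params, mode = "eval")
    p <- fw$probs[te, 2]
    per_fold[f, ] <- classification_metrics(labels[te], prob_to_label(p), p)
  }
  metrics_report(per_fold, plan,
                 config = list(strategy = strategy, k = k,
                               sim_threshold = sim_threshold,
                               seed = seed, strict = strict))
}

#' Three-strategy AD-GCN ablation
#'
#' Cross-validates the three graph-construction strategies with shared folds
#' and seeds: (1) similarity-only weighted graph, (2) similarity + kNN with
#' unit weights, (3) the full model with kNN expansion and cognitive weights.
#'
#' @inheritParams cross_validate_adgcn
#' @return list with `reports` (one `metrics_report` per strategy) and
#'   `comparison` (aggregate metric table).
#' @export
ablate_adgcn <- function(features, cognitive, labels, config = train_config(),
                         n_folds = 5, seed = 1, sim_threshold = 0.5, k = 10) {
  plan <- stratified_folds(as.integer(labels), n_folds, seed)
  strategies <- c("sim_only_w", "sim_knn_unweighted", "sim_knn_w")
  reports <- lapply(strategies, function(s)
    cross_validate_adgcn(features, cognitive, labels, strategy = s,
                         config = config, sim_threshold = sim_threshold,
                         k = k, fold_plan = plan, seed = seed))
  names(reports) <- strategies
  comparison <- do.call(rbind, lapply(strategies, function(s)
    data.frame(strategy = s, t(reports[[s]]$aggregate))))
  rownames(comparison) <- NULL
  list(reports = reports, comparison = comparison)
}
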