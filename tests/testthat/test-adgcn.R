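test_that("cosine similarity hits its geometric anchor points", {
  X <- rbind(c(1, 0), c(1, 0), c(0, 1), c(-1, 0))
  S <- composite_similarity(X)
  expect_equal(S[1, 2], 1)
  expect_equal(S[1, 3], 0)
  expect_equal(S[1, 4], -1)
  expect_equal(diag(S), rep(1, 4))
  expect_warning(composite_similarity(rbind(c(1, 1), c(0, 0))), "zero-norm")
})

test_that("edge thresholding is strictly greater-than", {
  S <- matrix(c(1, 0.5, 0.6,
                0.5, 1, 0.2,
                0.6, 0.2, 1), 3, 3)
  e <- threshold_edges(S, 0.5)
  expect_equal(e, matrix(c(1, 3), 1))   # the exact-0.5 pair is excluded
  expect_equal(nrow(threshold_edges(diag(3), 0.5)), 0)
  # all-identical samples give the complete graph
  Sm <- matrix(1, 4, 4)
  expect_equal(nrow(threshold_edges(Sm, 0.5)), 6)
})

test_that("kNN expansion matches hand enumeration and saturates", {
  X <- matrix(c(0, 1, 10), 3, 1)
  e <- knn_expand(X, k = 1)
  expect_equal(e, rbind(c(1, 2), c(2, 3)))
  # k covering all nodes yields the complete graph; complete stays complete
  e_full <- knn_expand(X, k = 2)
  expect_equal(nrow(e_full), 3)
  expect_equal(knn_expand(X, k = 1, existing_edges = e_full), e_full)
})

test_that("cognitive edge weights floor negatives and ignore affine scale", {
  C <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  edges <- rbind(c(1, 2), c(1, 3))
  w <- cognitive_edge_weights(C, edges)
  expect_equal(w, c(1, 1e-3))
  # per-sample affine rescaling leaves weights untouched
  C2 <- C; C2[1, ] <- 5 * C2[1, ] - 2
  expect_equal(cognitive_edge_weights(C2, edges), w)
  Cz <- rbind(C, d = c(2, 2, 2, 2))
  expect_warning(cognitive_edge_weights(Cz, rbind(c(1, 4))), "zero-variance")
})

test_that("graph strategies assemble the promised edge sets and weights", {
  set.seed(1)
  n <- 30
  X <- matrix(rnorm(n * 5), n)
  C <- matrix(rnorm(n * 12), n)
  g1 <- build_graph(X, C, "sim_only_w", k = 4)
  g2 <- build_graph(X, C, "sim_knn_unweighted", k = 4)
  g3 <- build_graph(X, C, "sim_knn_w", k = 4)
  expect_true(all(g2$weights == 1))
  # numeric strategy codes are accepted
  expect_equal(build_graph(X, C, 2, k = 4)$strategy, "sim_knn_unweighted")
  # kNN-expanded edge set contains the similarity-only edge set
  key <- function(e) paste(e[, 1], e[, 2])
  expect_true(all(key(g1$edges) %in% key(g3$edges)))
  expect_identical(key(g2$edges), key(g3$edges))
  expect_false(any(g1$edges[, 1] == g1$edges[, 2]))
})

test_that("normalized adjacency matches hand computation and is contractive", {
  g1 <- list(n_nodes = 1, edges = matrix(0, 0, 2), weights = numeric(0))
  expect_equal(normalize_adjacency(g1), matrix(1, 1, 1))
  g2 <- list(n_nodes = 2, edges = rbind(c(1, 2)), weights = 1)
  expect_equal(normalize_adjacency(g2), matrix(0.5, 2, 2))
  set.seed(2)
  for (r in 1:5) {
    n <- 15
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
    g <- list(n_nodes = n, edges = sel, weights = runif(nrow(sel)))
    ev <- eigen(normalize_adjacency(g), symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(ev), 1 + 1e-9)
    expect_gte(min(ev), -1 - 1e-9)
  }
})

test_that("forward pass honours degenerate and equivariance contracts", {
  set.seed(3)
  n <- 12; d <- 5
  X <- matrix(rnorm(n * d), n)
  C <- matrix(rnorm(n * 12), n)
  graph <- build_graph(X, C, "sim_knn_w", k = 3)
  Ahat <- normalize_adjacency(graph)
  M <- adgcn:::neighbor_mean_operator(graph)
  params <- adgcn_init(d, seed = 1)
  # zero parameters: scores reduce to the output bias at every node
  p0 <- params
  for (nm in c("W1", "W2s", "W2n", "Wout")) p0[[nm]] <- p0[[nm]] * 0
  p0$bout <- c(0.3, -0.2)
  fw0 <- adgcn_forward(Ahat, M, X, p0, mode = "eval")
  expect_equal(fw0$scores, matrix(rep(c(0.3, -0.2), each = n), n))
  # permutation equivariance
  fw <- adgcn_forward(Ahat, M, X, params, mode = "train")
  perm <- sample(n)
  fwp <- adgcn_forward(Ahat[perm, perm], M[perm, , drop = FALSE][, perm],
                       X[perm, ], params, mode = "train")
  expect_equal(fwp$probs, fw$probs[perm, ], tolerance = 1e-10)
  # single isolated node: neighbour term vanishes
  g1 <- list(n_nodes = 1, edges = matrix(0, 0, 2), weights = numeric(0))
  fw1 <- adgcn_forward(normalize_adjacency(g1),
                       adgcn:::neighbor_mean_operator(g1),
                       X[1, , drop = FALSE], params, mode = "eval")
  expect_equal(dim(fw1$scores), c(1, 2))
  expect_equal(unname(fw1$cache$N1), matrix(0, 1, params$hidden[1]))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(4)
  n <- 8; d <- 4
  X <- matrix(rnorm(n * d), n)
  C <- matrix(rnorm(n * 12), n)
  graph <- build_graph(X, C, "sim_knn_w", k = 2)
  Ahat <- normalize_adjacency(graph)
  M <- adgcn:::neighbor_mean_operator(graph)
  y <- rep(c(0L, 1L), each = n / 2)
  mask <- seq_len(n)
  params <- adgcn_init(d, seed = 2)
  loss_of <- function(p) {
    fw <- adgcn_forward(Ahat, M, X, p, mode = "train")
    -mean(log(pmax(fw$probs[cbind(mask, y[mask] + 1L)], 1e-12)))
  }
  fw <- adgcn_forward(Ahat, M, X, params, mode = "train")
  gr <- adgcn:::adgcn_backward(fw, M, y, mask, params)
  eps <- 1e-5
  for (nm in c("W1", "b1", "g1", "be1", "W2s", "W2n", "b2", "Wout", "bout")) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training descends, converges on separable data, reproduces", {
  set.seed(5)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(y * 2 - 1 + rnorm(n, 0, 0.2), matrix(rnorm(n * 3), n))
  C <- matrix(rnorm(n * 12), n) + outer(y - 0.5, rep(c(2, -2), 6))
  graph <- build_graph(X, C, "sim_knn_w", k = 5)
  cfg <- train_config(epochs = 200, seed = 3)
  tr <- adgcn_train(graph, adgcn:::zscore_cols(X), y, seq_len(n), cfg)
  expect_lte(tr$history[min(50, length(tr$history))], tr$history[1])
  fw <- adgcn_forward(tr$Ahat, tr$M, adgcn:::zscore_cols(X), tr$params, "eval")
  expect_equal(mean((fw$probs[, 2] > 0.5) == y), 1)
  tr2 <- adgcn_train(graph, adgcn:::zscore_cols(X), y, seq_len(n), cfg)
  expect_identical(tr$history, tr2$history)
})

test_that("the fitted-model interface behaves like a classed estimator", {
  set.seed(6)
  n <- 50
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sig = y + rnorm(n, 0, 0.3), matrix(rnorm(n * 2), n))
  C <- matrix(rnorm(n * 12), n) + outer(y - 0.5, rep(c(1.5, -1.5), 6))
  fit <- adgcn_fit(X, C, y, config = train_config(epochs = 80, seed = 1))
  expect_s3_class(fit, "adgcn")
  expect_output(print(fit), "AD-GCN")
  sm <- summary(fit)
  expect_gte(sm$train[["accuracy"]], 0.9)
  expect_length(predict(fit), n)
  expect_true(all(predict(fit, type = "class") %in% c(0L, 1L)))
  expect_equal(predict(fit, type = "prob"), fitted(fit))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("cross-validation and ablation share folds and record provenance", {
  co <- small_cohort(41, n = 60)
  X <- cbind(co$cognitive[, 1:3],
             co$methylation[, co$truth$informative_probes])
  cfg <- train_config(epochs = 60, seed = 2)
  cv <- cross_validate_adgcn(X, co$cognitive, co$labels, config = cfg,
                             n_folds = 3, seed = 2, k = 5)
  expect_equal(cv$config$strategy, "sim_knn_w")
  expect_equal(cv$config$k, 5)
  expect_equal(cv$config$seed, 2)
  expect_equal(nrow(cv$per_fold), 3)
  ab <- ablate_adgcn(X, co$cognitive, co$labels, config = cfg, n_folds = 3,
                     seed = 2, k = 5)
  plans <- lapply(ab$reports, function(r) r$fold_plan)
  expect_identical(plans[[1]], plans[[2]])
  expect_identical(plans[[2]], plans[[3]])
  ab2 <- ablate_adgcn(X, co$cognitive, co$labels, config = cfg, n_folds = 3,
                      seed = 2, k = 5)
  expect_identical(ab$comparison, ab2$comparison)
})

test_that("shuffled labels leave cross-validated MCC at chance", {
  co <- small_cohort(51, n = 60)
  X <- cbind(co$cognitive[, 1:3],
             co$methylation[, co$truth$informative_probes])
  mccs <- vapply(1:3, function(sd_) {
    y_perm <- adgcn:::with_seed(sd_, sample(co$labels))
    cv <- cross_validate_adgcn(X, co$cognitive, y_perm,
                               config = train_config(epochs = 60, seed = sd_),
                               n_folds = 3, seed = sd_, k = 5)
    cv$aggregate[["mcc"]]
  }, numeric(1))
  expect_gte(median(mccs), -0.2)
  expect_lte(median(mccs), 0.2)
})
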