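test_that("Welch probe test: null calibration, signal, degenerate probes", {
  set.seed(1)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  beta0 <- matrix(runif(n * 800, 0.2, 0.8), n)
  p0 <- differential_probe_test(beta0, y)
  expect_lt(unname(ks_two_sample(p0, seq(0, 1, length.out = 2000))["D"]), 0.1)
  # strong shift: 0.4 on sd 0.01 -> essentially zero p
  strong <- matrix(rnorm(n, 0.3 + 0.4 * y, 0.01), n, 1)
  expect_lt(differential_probe_test(strong, y), 1e-10)
  expect_equal(differential_probe_test(matrix(0.5, n, 1), y), 1)
})

test_that("BH adjustment matches the literal quadratic step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      cand <- vapply(seq_len(m), function(j)
        if (p[o[j]] >= p[o[i]]) p[o[j]] * m / j else Inf, numeric(1))
      q[o[i]] <- min(1, min(cand))
    }
    q
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  for (r in 1:5) {
    p <- runif(sample(3:100, 1))^2
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("beta KNN imputation fills from nearest samples and clips", {
  b <- matrix(c(0.2, 0.2, 0.2, 0.2,
                0.5, 0.5, 0.5, 0.5,
                0.8, 0.8, 0.8, NA), 4, 3)
  expect_identical(knn_impute_beta(b[, 1:2], k = 2), b[, 1:2])
  # identical samples: the gap takes the common value
  bi <- matrix(0.4, 5, 3); bi[2, 1] <- NA
  expect_equal(knn_impute_beta(bi, k = 2)[2, 1], 0.4)
  # k = n-1 with tied distances equals the mean of the other samples
  b2 <- matrix(c(1, 1, 1,
                 0.2, 0.4, NA,
                 1, 1, 1,
                 0.6, 0.6, 0.6), 4, 3, byrow = TRUE)
  # distances from row 2 on shared-observed probes tie only by content;
  # with k = 3 all other rows average into the gap
  got <- knn_impute_beta(b2, k = 3)[2, 3]
  expect_equal(got, mean(c(1, 1, 0.6)))
  expect_warning(knn_impute_beta(cbind(c(0.1, 0.2), c(NA, NA)), k = 1),
                 "missing in all samples")
})

test_that("prefilter enforces the strict q cut and island flag", {
  q <- c(0.0009, 0.0009, 0.001, 0.5)
  isl <- c(TRUE, FALSE, TRUE, TRUE)
  keep <- prefilter_probes(q, isl)
  expect_equal(keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(prefilter_probes(c(0.5, 0.9), c(TRUE, TRUE)), "no probe")
  # null panel: survivors are at most a handful
  set.seed(3)
  y <- rep(c(0, 1), each = 100)
  b0 <- matrix(runif(200 * 1000, 0.2, 0.8), 200)
  q0 <- bh_adjust(differential_probe_test(b0, y))
  expect_lte(sum(q0 < 0.001), 3)
})

test_that("Fisher score matches its defining formula", {
  fisher_oracle <- function(X, y) {
    mu <- colMeans(X)
    num <- den <- 0
    for (cl in unique(y)) {
      nc <- sum(y == cl)
      num <- num + nc * (colMeans(X[y == cl, , drop = FALSE]) - mu)^2
      den <- den + nc * apply(X[y == cl, , drop = FALSE], 2, var)
    }
    unname(num / (den + 1e-12))
  }
  # hand instance: class 0 = {0,2}, class 1 = {5,7}: F = d^2/(4v) = 25/8
  X <- matrix(c(0, 2, 5, 7), 4, 1); y <- c(0, 0, 1, 1)
  expect_equal(fisher_score(X, y), 25 / 8)
  expect_equal(fisher_score(matrix(3, 10, 2), rep(c(0, 1), 5)), c(0, 0))
  set.seed(4)
  X2 <- matrix(rnorm(200), 20); y2 <- rep(c(0, 1), each = 10)
  expect_equal(fisher_score(X2, y2), fisher_oracle(X2, y2))
  perm <- sample(20)
  expect_equal(fisher_score(X2[perm, ], y2[perm]), fisher_score(X2, y2))
})

test_that("top-quantile mask keeps the stated count with index tie-breaks", {
  expect_equal(top_quantile_mask(c(4, 3, 2, 1), 0.25), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(top_quantile_mask(runif(100), 0.25)), 25)
  expect_true(all(top_quantile_mask(rnorm(10), 1)))
  # ties at the cut resolve to earlier features
  expect_equal(top_quantile_mask(c(1, 1, 1, 1), 0.5), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("stump information gain equals exhaustive threshold enumeration", {
  ig_oracle <- function(x, y) {
    H <- function(v) {
      p <- table(v) / length(v); p <- p[p > 0]; -sum(p * log2(p))
    }
    ux <- sort(unique(x))
    if (length(ux) < 2) return(0)
    best <- Inf
    for (t in (ux[-1] + ux[-length(ux)]) / 2) {
      l <- x <= t
      best <- min(best, mean(l) * H(y[l]) + mean(!l) * H(y[!l]))
    }
    max(H(y) - best, 0)
  }
  expect_equal(stump_information_gain(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(stump_information_gain(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0)
  expect_equal(stump_information_gain(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  set.seed(5)
  for (r in 1:10) {
    x <- sample(1:6, 30, replace = TRUE) + rnorm(30, 0, 0.01)
    y <- rbinom(30, 1, 0.5)
    expect_equal(stump_information_gain(x, y), ig_oracle(x, y))
  }
})

test_that("random-forest ranking finds a planted feature and is seeded", {
  hits <- 0
  for (sd_ in 1:20) {
    set.seed(sd_)
    n <- 300
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * 20, 0, 0.05), n)
    X[, 7] <- X[, 7] + 0.3 * y
    colnames(X) <- sprintf("f%02d", 1:20)
    rk <- rf_rank(X, y, n_top = 5, n_trees = 100, seed = sd_)
    hits <- hits + (rk$feature[1] == "f07")
  }
  expect_gte(hits, 18)
  # pure noise: importance mass roughly uniform
  ratios <- vapply(1:10, function(sd_) {
    set.seed(sd_)
    Xn <- matrix(rnorm(100 * 20), 100)
    colnames(Xn) <- sprintf("f%02d", 1:20)
    rk <- rf_rank(Xn, rbinom(100, 1, 0.5), n_top = 20, n_trees = 100, seed = sd_)
    max(rk$importance) / mean(rk$importance)
  }, numeric(1))
  expect_lt(max(ratios), 5)
  set.seed(9)
  X <- matrix(rnorm(60 * 8), 60); colnames(X) <- letters[1:8]
  y <- rbinom(60, 1, 0.5)
  expect_identical(rf_rank(X, y, seed = 11), rf_rank(X, y, seed = 11))
})

test_that("incremental SVM curve behaves at the extremes", {
  set.seed(6)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  # single perfectly separating feature
  X1 <- cbind(sep = y * 2 - 1 + rnorm(n, 0, 0.01))
  r1 <- incremental_svm_eval(X1, y, seed = 1)
  expect_equal(unname(unlist(r1[1, c("g_mean", "accuracy", "precision", "f1")])),
               rep(1, 4))
  # pure noise stays near chance at every prefix
  accs <- vapply(1:5, function(sd_) {
    set.seed(sd_)
    Xn <- matrix(rnorm(n * 5), n)
    median(incremental_svm_eval(Xn, y, seed = sd_)$accuracy)
  }, numeric(1))
  expect_gte(median(accs), 0.35); expect_lte(median(accs), 0.65)
})

test_that("the full marker cascade recovers planted island probes", {
  co <- small_cohort(31, n = 250)
  # the q gate is calibrated for cohort-scale power; this fixture uses a
  # permissive cut so the same cascade runs at reduced size
  sel <- select_methylation_markers(co$methylation, co$labels,
                                    co$probe_meta$island, q_max = 0.1,
                                    n_final = 6, seed = 1)
  planted <- colnames(co$methylation)[co$truth$informative_probes]
  expect_gte(sum(sel$selected %in% planted), 4)
  expect_lte(sel$balance$ir_after, sel$balance$ir_before)
  expect_equal(unname(sel$stage_counts["final"]), 6)
})
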