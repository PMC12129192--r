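test_that("block LD matrices: degenerate and sampling-noise behaviour", {
  set.seed(1)
  g <- cbind(a = rbinom(200, 2, 0.3))
  ld1 <- ld_from_genotypes(g, blocks = 1)
  expect_equal(unname(ld1$R[["1"]]), matrix(1, 1, 1))
  # duplicated SNP: off-diagonal r = 1 (up to the unit-diagonal shrink)
  g2 <- cbind(a = g[, 1], b = g[, 1])
  ld2 <- ld_from_genotypes(g2, blocks = c(1, 1))
  expect_equal(ld2$R[["1"]]["a", "b"], 1, tolerance = 1e-5)
  # constant SNP gets zero correlation by definition
  g3 <- cbind(a = g[, 1], const = rep(1L, 200))
  ld3 <- ld_from_genotypes(g3, blocks = c(1, 1))
  expect_equal(ld3$R[["1"]]["a", "const"], 0, tolerance = 1e-6)
  # independent SNPs at n = 1000: mean |off-diagonal| below sampling bound
  set.seed(2)
  G <- sapply(1:20, function(j) rbinom(1000, 2, 0.4))
  colnames(G) <- sprintf("s%02d", 1:20)
  R <- ld_from_genotypes(G, rep(1, 20))$R[["1"]]
  expect_lt(mean(abs(R[upper.tri(R)])), 0.05)
})

test_that("greedy clumping matches a literal brute-force oracle", {
  clump_oracle <- function(stats, R, r2) {
    alive <- stats$SNP[order(stats$P, stats$SNP)]
    idx <- character(0)
    while (length(alive) > 0) {
      s <- alive[1]
      idx <- c(idx, s)
      drop <- alive[R[s, alive]^2 >= r2]
      alive <- setdiff(alive, union(s, drop))
    }
    idx
  }
  # worked 5-SNP instance with a printed correlation and p grid
  snps <- paste0("s", 1:5)
  R <- matrix(c(1, .9, .1, 0, 0,
                .9, 1, .2, 0, 0,
                .1, .2, 1, .8, .1,
                0, 0, .8, 1, 0,
                0, 0, .1, 0, 1), 5, 5, dimnames = list(snps, snps))
  stats <- data.frame(SNP = snps, A1 = "G", BETA = 1, SE = 1,
                      P = c(0.04, 0.001, 0.01, 0.2, 0.05), N = 100)
  ld <- list(R = list(`1` = R), block_of = setNames(rep(1, 5), snps),
             snps = snps)
  class(ld) <- "ld_blocks"
  got <- clump(stats, ld, r2_threshold = 0.1)
  expect_equal(got, clump_oracle(stats, R, 0.1))
  expect_equal(got, c("s2", "s3", "s5"))   # frozen from the oracle
  # all SNPs mutually r2 = 1: only the smallest-p survives
  R1 <- matrix(1, 5, 5, dimnames = list(snps, snps))
  ld1 <- ld; ld1$R <- list(`1` = R1)
  expect_equal(clump(stats, ld1, 0.1), "s2")
  # fully independent SNPs: everything survives
  ld0 <- ld; ld0$R <- list(`1` = diag(5)); dimnames(ld0$R[["1"]]) <- list(snps, snps)
  expect_length(clump(stats, ld0, 0.1), 5)
  expect_equal(clump(stats[0, ], ld, 0.1), character(0))
})

test_that("LDpred-inf equals closed forms and a dense solver oracle", {
  snps <- paste0("s", 1:8)
  set.seed(3)
  stats <- data.frame(SNP = snps, A1 = "G", BETA = rnorm(8), SE = 0.1,
                      P = runif(8), N = 400)
  # identity LD: w_j = beta_j / (1 + M/(N h2))
  ldI <- list(R = list(`1` = diag(8)), block_of = setNames(rep(1, 8), snps),
              snps = snps)
  dimnames(ldI$R[["1"]]) <- list(snps, snps)
  class(ldI) <- "ld_blocks"
  w <- ldpred_inf(stats, ldI, n_gwas = 400, h2 = 0.5)
  expect_equal(unname(w), stats$BETA / (1 + 8 / (400 * 0.5)), tolerance = 1e-12)
  # random 8-SNP block vs direct dense solve
  A <- matrix(rnorm(64), 8); R <- cov2cor(crossprod(A) + diag(8))
  dimnames(R) <- list(snps, snps)
  ldR <- ldI; ldR$R <- list(`1` = R)
  w2 <- ldpred_inf(stats, ldR, n_gwas = 400, h2 = 0.3)
  lam <- 8 / (400 * 0.3)
  expect_equal(unname(w2), as.numeric(solve(R + diag(lam, 8), stats$BETA)),
               tolerance = 1e-10)
  # M/(N h2) -> 0 limit: weights approach the joint effects D^-1 beta
  w3 <- ldpred_inf(stats, ldR, n_gwas = 1e9, h2 = 1)
  expect_equal(unname(w3), as.numeric(solve(R, stats$BETA)), tolerance = 1e-5)
})

test_that("block-wise LDpred-inf equals the whole-panel dense solve", {
  set.seed(4)
  co <- small_cohort(4, n = 120)
  G <- co$genotypes[, 1:48]
  G[is.na(G)] <- 1
  snps <- colnames(G)
  stats <- data.frame(SNP = snps, A1 = "G", BETA = rnorm(48), SE = 0.1,
                      P = runif(48), N = 120)
  blocks8 <- rep(1:8, each = 6)
  ld_blocked <- ld_from_genotypes(G, blocks8)
  ld_whole <- ld_from_genotypes(G, rep(1, 48))
  # whole-panel D is block-diagonal when cross-block correlation is zeroed
  Dw <- ld_whole$R[["1"]]
  for (b in 1:8) {
    in_b <- blocks8 == b
    Dw[in_b, !in_b] <- 0
  }
  lam <- 48 / (120 * 0.3)
  oracle <- solve(Dw + diag(lam, 48), stats$BETA)
  w <- ldpred_inf(stats, ld_blocked, n_gwas = 120, h2 = 0.3)
  expect_equal(unname(w[snps]), as.numeric(oracle), tolerance = 1e-10)
})

test_that("polygenic scoring is the weighted allele sum", {
  G <- cbind(s1 = c(2, 0, 1), s2 = c(1, 2, 0))
  expect_equal(prs_score(G, c(s1 = 0.5, s2 = -1)), c(0, -2, 0.5))
  expect_equal(prs_score(G, c(s1 = 0, s2 = 0)), c(0, 0, 0))
  expect_equal(prs_score(G, c(s2 = 1)), G[, "s2"], ignore_attr = TRUE)
  expect_error(prs_score(G, c(s9 = 1)), "absent")
  # missing dosage falls back to the per-SNP mean
  Gm <- G; Gm[1, 1] <- NA
  expect_equal(prs_score(Gm, c(s1 = 1))[1], mean(c(0, 1)))
})

test_that("Nagelkerke R2 follows the rescaled Cox-Snell formula", {
  expect_equal(nagelkerke_r2(-10, -10, 50), 0)
  # perfect prediction of a balanced pair: CS = 0.75, max = 0.75 -> 1
  ll0 <- 2 * log(0.5)
  expect_equal(1 - exp(2 * (ll0 - 0) / 2), 0.75)
  expect_equal(nagelkerke_r2(0, ll0, 2), 1)
  # monotone nondecreasing in the full-model likelihood
  r2s <- vapply(seq(-20, -1, length.out = 10),
                function(ll) nagelkerke_r2(ll, -25, 40), numeric(1))
  expect_true(all(diff(r2s) >= 0))
})

test_that("P+T tunes the threshold and degenerates correctly", {
  set.seed(6)
  n <- 300
  g <- cbind(causal = rbinom(n, 2, 0.4))
  y <- rbinom(n, 1, plogis(-2 + 3 * g[, 1]))
  stats <- association_scan(g, y)
  ld <- ld_from_genotypes(g, 1)
  res <- prs_pt(g, y, stats, ld, p_grid = 1)
  expect_equal(cor(res$scores, g[, 1]), 1)   # single-SNP score is the dosage
  expect_equal(res$tuning$n_snps, 1)
  expect_error(prs_pt(g, y, stats, ld, p_grid = 1e-300),
               "no SNP passes")
  # reproducibility of the tuned threshold
  res2 <- prs_pt(g, y, stats, ld, p_grid = 1)
  expect_identical(res$tuning, res2$tuning)
})

test_that("KS statistic matches ECDF enumeration and rank invariance holds", {
  expect_equal(unname(ks_two_sample(1:5, 1:5)["D"]), 0)
  expect_equal(unname(ks_two_sample(1:5, 11:15)["D"]), 1)
  expect_equal(unname(ks_two_sample(c(1, 2, 3), c(1, 2, 4))["D"]), 1 / 3,
               tolerance = 1e-12)
  # affine rescaling of both samples leaves D unchanged; AUC likewise
  set.seed(7)
  a <- rnorm(40); b <- rnorm(40, 0.8)
  z <- function(x) (x - mean(c(a, b))) / sd(c(a, b))
  expect_equal(ks_two_sample(a, b)["D"], ks_two_sample(z(a), z(b))["D"])
  y <- rep(c(0, 1), each = 40); s <- c(a, b)
  expect_equal(auc_rank(y, s), auc_rank(y, 3 * s + 7))
})

test_that("clinical + PRS evaluation reports both AUCs honestly", {
  set.seed(8)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  bdi <- data.frame(age = rnorm(n, 73, 7), edu = rnorm(n, 16, 2))
  # null PRS and null clinical: both models near chance
  r0 <- evaluate_bdi_prs(bdi, rnorm(n), y, seed = 1)
  expect_gt(r0$mean_auc_bdi, 0.4); expect_lt(r0$mean_auc_bdi, 0.6)
  expect_gt(r0$mean_auc_bdi_prs, 0.4); expect_lt(r0$mean_auc_bdi_prs, 0.6)
  # perfectly separating PRS drives the joint model to AUC 1
  r1 <- evaluate_bdi_prs(bdi, y * 10 + rnorm(n, 0, 0.01), y, seed = 1)
  expect_equal(r1$mean_auc_bdi_prs, 1)
})
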