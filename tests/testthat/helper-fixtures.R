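# Shared fixtures: small cohorts and toy matrices built in code.

small_cohort <- function(seed = 1, n = 80, ...) {
  generate_cohort(cohort_config(
    n_samples = n, n_snps = 60, n_ld_blocks = 10, n_causal_snps = 4,
    snp_effect_sd = 0.5, n_probes = 120, n_informative_probes = 6,
    island_fraction = 0.4, seed = seed, ...))
}

# two Gaussian clusters in 2-D with controllable overlap and imbalance
two_cluster_toy <- function(n_maj = 30, n_min = 10, gap = 2, sd = 1, seed = 1) {
  adgcn:::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_maj * 2, 0, sd), ncol = 2),
               matrix(rnorm(n_min * 2, gap, sd), ncol = 2))
    list(X = X, y = c(rep(0L, n_maj), rep(1L, n_min)))
  })
}

# brute-force borderline taxonomy oracle (all-pairs distances, literal rule)
boundary_oracle <- function(X, y, m = 5) {
  n <- nrow(X)
  mc <- names(which.min(table(y)))
  cat_out <- list()
  danger_nb <- integer(0)
  for (i in which(y == mc)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(m)]
    n_maj <- sum(y[nb] != mc)
    cat_out[[as.character(i)]] <-
      if (n_maj == m) "NOISE" else if (n_maj >= m / 2) "DANGER" else "SAFE"
    if (cat_out[[as.character(i)]] == "DANGER")
      danger_nb <- c(danger_nb, nb[y[nb] != mc])
  }
  list(category = unlist(cat_out), boundary_majority = sort(unique(danger_nb)))
}
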