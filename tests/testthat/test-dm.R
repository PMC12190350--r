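# independent brute-force DM log-likelihood for oracle checks
dm_ll_oracle <- function(y, pi, gamma) {
  n <- rowSums(y)
  a <- gamma * pi
  sum(vapply(seq_len(nrow(y)), function(u) {
    lgamma(gamma) - lgamma(n[u] + gamma) +
      sum(lgamma(y[u, ] + a) - lgamma(a))
  }, numeric(1)))
}

test_that("precision estimation recovers the simulated concentration", {
  ## no overdispersion: proportional splits push gamma to the upper bound
  y <- matrix(50, 6, 2)
  expect_equal(as.numeric(estimate_precision(y)), 1e6)

  ## parameter recovery from DM data
  set.seed(2)
  y2 <- rdirmultinom(20, 500, c(0.5, 0.3, 0.2), gamma = 30)
  g <- as.numeric(estimate_precision(y2))
  expect_gte(g, 15); expect_lte(g, 60)

  ## maximal overdispersion
  y3 <- rbind(c(100, 0), c(0, 100))
  g3 <- as.numeric(estimate_precision(y3))
  expect_lt(g3, 5)
  ## grid-search oracle: no (pi, gamma) pair on a dense grid beats the
  ## profile-likelihood optimum
  grid_best <- max(vapply(seq(0.05, 0.95, by = 0.01), function(p) {
    max(vapply(exp(seq(log(0.01), log(1e6), length.out = 200)), function(gam) {
      dm_ll_oracle(y3, c(p, 1 - p), gam)
    }, numeric(1)))
  }, numeric(1)))
  expect_gte(attr(estimate_precision(y3), "loglik"), grid_best - 1e-3)
})

test_that("the gene-level LRT behaves at the null and detects a hard switch", {
  ## identical group compositions, large counts: no signal
  y <- matrix(rep(c(400, 600), each = 8), 8, 2)
  fit <- fit_dm_gene(y, rep(c("a", "b"), 4))
  expect_lt(fit$lr_stat, 0.5)
  expect_gt(fit$p_value, 0.5)
  expect_equal(sum(fit$pi_null), 1, tolerance = 1e-9)
  expect_equal(unname(rowSums(fit$pi_full)), c(1, 1), tolerance = 1e-9)

  ## hard switch (90,10)x5 vs (10,90)x5
  y2 <- rbind(matrix(rep(c(90, 10), each = 5), 5, 2),
              matrix(rep(c(10, 90), each = 5), 5, 2))
  g2 <- rep(c("a", "b"), each = 5)
  fit2 <- fit_dm_gene(y2, g2)
  expect_lt(fit2$p_value, 1e-6)
  ## verify the maximized log-likelihoods against a dense grid oracle
  grid_null <- max(vapply(seq(0.01, 0.99, by = 0.005), function(p) {
    dm_ll_oracle(y2, c(p, 1 - p), fit2$gamma)
  }, numeric(1)))
  expect_gte(fit2$loglik_null, grid_null - 1e-3)
  grid_full <- max(vapply(seq(0.01, 0.99, by = 0.005), function(p) {
    dm_ll_oracle(y2[1:5, ], c(p, 1 - p), fit2$gamma)
  }, numeric(1))) +
    max(vapply(seq(0.01, 0.99, by = 0.005), function(p) {
      dm_ll_oracle(y2[6:10, ], c(p, 1 - p), fit2$gamma)
    }, numeric(1)))
  expect_gte(fit2$loglik_full, grid_full - 1e-3)

  ## degenerate inputs
  expect_false(fit_dm_gene(matrix(5, 4, 1), rep(c("a", "b"), 2))$testable)
  expect_false(fit_dm_gene(rbind(c(0, 0), c(3, 4)), c("a", "b"))$testable)
})

test_that("statistics are invariant to unit permutations", {
  set.seed(3)
  y <- rdirmultinom(12, 300, c(0.6, 0.3, 0.1), gamma = 20)
  g <- rep(c("a", "b"), each = 6)
  fit1 <- fit_dm_gene(y, g)
  perm <- sample(12)
  fit2 <- fit_dm_gene(y[perm, ], g[perm])
  expect_equal(fit1$lr_stat, fit2$lr_stat, tolerance = 1e-6)
  expect_equal(fit1$gamma, fit2$gamma, tolerance = 1e-4)
})

test_that("at the multinomial limit the LRT approaches the pooled G-test", {
  set.seed(4)
  y <- rbind(t(rmultinom(6, 400, c(0.5, 0.35, 0.15))),
             t(rmultinom(6, 400, c(0.3, 0.5, 0.2))))
  g <- rep(c("a", "b"), each = 6)
  fit <- fit_dm_gene(y, g, gamma = 1e6)
  ## classical multinomial G statistic on pooled per-group counts
  pooled <- rbind(colSums(y[1:6, ]), colSums(y[7:12, ]))
  expect_g <- 0
  phat <- colSums(pooled) / sum(pooled)
  for (r in 1:2) {
    e <- sum(pooled[r, ]) * phat
    expect_g <- expect_g + 2 * sum(pooled[r, ] * log(pooled[r, ] / e))
  }
  expect_equal(fit$lr_stat, expect_g, tolerance = 0.02 * expect_g)
})

test_that("feature-level tests are symmetric and sign-consistent", {
  y <- rbind(matrix(rep(c(80, 20), each = 4), 4, 2),
             matrix(rep(c(30, 70), each = 4), 4, 2))
  colnames(y) <- c("I1", "I2")
  g <- rep(c("a", "b"), each = 4)
  fit <- fit_dm_gene(y, g)
  ft <- feature_level_test(fit, y, g, focus = "a")
  ## two-isoform switch: equal p, opposite equal-magnitude effects
  expect_equal(ft$p_value[1], ft$p_value[2], tolerance = 1e-6)
  expect_equal(ft$effect[1], -ft$effect[2], tolerance = 1e-12)
  expect_equal(ft$direction, c("high usage", "low usage"))

  ## a non-switching isoform inside a switching gene stays null:
  ## usages a = (0.6, 0.2, 0.2), b = (0.2, 0.2, 0.6)
  ua <- c(0.6, 0.2, 0.2); ub <- c(0.2, 0.2, 0.6)
  y3 <- rbind(t(sapply(1:6, function(i) round(500 * ua))),
              t(sapply(1:6, function(i) round(500 * ub))))
  colnames(y3) <- c("I1", "I2", "I3")
  g3 <- rep(c("a", "b"), each = 6)
  fit3 <- fit_dm_gene(y3, g3)
  ft3 <- feature_level_test(fit3, y3, g3, focus = "a")
  expect_gt(ft3$p_value[ft3$isoform == "I2"], 0.9)
  expect_equal(ft3$effect[ft3$isoform == "I2"], 0, tolerance = 1e-9)
  ## effect signs match observed usage differences
  expect_gt(ft3$effect[ft3$isoform == "I1"], 0)
  expect_lt(ft3$effect[ft3$isoform == "I3"], 0)
})

test_that("the scan aggregates, adjusts, and validates contrasts", {
  fx <- tiny_sim()
  pb <- pseudobulk(fx$counts, fx$cells)
  grp <- ifelse(pb$units$cell_type == "neuron", "neuron", "rest")
  scan <- run_usage_scan(pb, fx$catalog, grp, focus = "neuron")
  gt <- scan$gene_table
  expect_true(all(gt$p_adj >= gt$p_value - 1e-12, na.rm = TRUE))
  it <- scan$isoform_table
  expect_true(all((it$effect > 0) == (it$direction == "high usage")))
  ## single-group contrast is a configuration error
  expect_error(run_usage_scan(pb, fx$catalog, rep("x", nrow(pb$counts))),
               "2 groups")
  ## a contrast naming an absent group collapses to one group
  expect_error(run_usage_scan(pb, fx$catalog,
                              ifelse(pb$units$cell_type == "no_such", "a", "b")),
               "2 groups")
})
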