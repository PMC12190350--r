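test_that("site binning matches the worked examples and mirrors on strand", {
  expect_equal(bin_positions(c(100, 145, 160), "+", 20), c(0L, 2L, 3L))
  expect_equal(bin_positions(c(100, 145), "-", 20), c(2L, 0L))
  expect_equal(bin_positions(c(2000, 2074, 2075), "+", 75), c(0L, 0L, 1L))
  expect_equal(bin_positions(c(2000, 2074, 2075), "-", 75), c(1L, 0L, 0L))
  expect_equal(bin_positions(500, "+", 20), 0L)
})

test_that("the weighted attribute equals brute-force sum(u * a)", {
  expect_equal(weighted_attribute(1, 500), 500)
  expect_equal(weighted_attribute(c(0.7, 0.3), c(1000, 500)), 850)
  expect_equal(weighted_attribute(c(0.5, 0.5), c(1, -1)), 0)

  set.seed(8)
  for (i in 1:100) {
    J <- sample(2:6, 1)
    u <- rgamma(J, 1); u <- u / sum(u)
    a <- rnorm(J, 0, 100)
    expect_equal(weighted_attribute(u, a), sum(u * a), tolerance = 1e-12)
  }
  ## linearity in usages and order invariance
  u <- c(0.2, 0.3, 0.5); a <- c(10, -5, 2)
  perm <- c(3, 1, 2)
  expect_equal(weighted_attribute(u[perm], a[perm]), weighted_attribute(u, a))
  ## coding-score sum rule: |A| <= 1
  expect_lte(abs(weighted_attribute(u, c(1, -1, 1))), 1)

  ## missing attributes: excluded unless renormalized
  expect_true(is.na(weighted_attribute(c(0.5, 0.5), c(NA, 100))))
  expect_equal(weighted_attribute(c(0.5, 0.5), c(NA, 100), renormalize = TRUE), 100)
  expect_true(is.na(weighted_attribute(c(0.5, 0.5), c(NA_real_, NA_real_),
                                       renormalize = TRUE)))
})

test_that("attribute deltas follow the declared sign conventions", {
  a_tss <- c(0, 3)          # isoform 1 at the most upstream TSS
  u_ref <- c(0.5, 0.5)
  u_up <- c(0.9, 0.1)       # shift toward the upstream-TSS isoform
  d <- attribute_delta(u_up, u_ref, a_tss, "tss_bin")
  expect_gt(d$delta, 0)     # negation: upstream shift is positive

  a_pas <- c(0, 4)
  u_down <- c(0.1, 0.9)     # shift toward the downstream PAS
  expect_gt(attribute_delta(u_down, u_ref, a_pas, "pas_bin")$delta, 0)

  ## identity
  for (at in c("length", "tss_bin", "pas_bin", "coding_score")) {
    expect_equal(attribute_delta(u_ref, u_ref, c(5, 9), at)$delta, 0)
  }

  ## one-vs-rest reference is the mean of the other groups' A values
  ref_mat <- rbind(c(1, 0), c(0, 1))
  d2 <- attribute_delta(c(0.5, 0.5), ref_mat, c(100, 200), "length")
  expect_equal(d2$A_ref, 150)
  expect_equal(d2$delta, 0)
})

test_that("pair-change classification picks extremes and compares attributes", {
  attrs <- data.frame(
    isoform_id = c("I1", "I2", "I3"), gene_id = "G1",
    length = c(500, 500, 900), exon_count = c(2, 2, 2),
    coding_score = c(1, 1, 1), tss_bin = c(0, 3, 0), pas_bin = c(0, 0, 0),
    stringsAsFactors = FALSE)
  fr <- data.frame(isoform = c("I1", "I2", "I3"),
                   effect = c(0.4, -0.4, 0.0), stringsAsFactors = FALSE)
  expect_equal(classify_pair_change(fr, attrs), "TSS")

  attrs2 <- attrs; attrs2$tss_bin <- 0; attrs2$exon_count <- c(2, 5, 2)
  expect_equal(classify_pair_change(fr, attrs2), "exon count")

  ## identical pair -> empty set; relabeling untested isoforms changes nothing
  attrs3 <- attrs; attrs3$tss_bin <- 0
  expect_length(classify_pair_change(fr, attrs3), 0)
  fr_perm <- fr[c(2, 3, 1), ]
  expect_equal(classify_pair_change(fr_perm, attrs), "TSS")

  expect_null(classify_pair_change(fr[1, , drop = FALSE], attrs))
})

test_that("delta correlations recover monotone and planted couplings", {
  g <- sprintf("G%03d", 1:10)
  d <- rbind(
    data.frame(gene_id = g, attribute = "length", delta = 1:10),
    data.frame(gene_id = g, attribute = "pas_bin", delta = 2 * (1:10)))
  res <- delta_correlations(d)
  expect_equal(res$rho["length", "pas_bin"], 1)
  expect_equal(res$n["length", "pas_bin"], 10)

  set.seed(9)
  g2 <- sprintf("G%04d", 1:2000)
  x <- rnorm(2000); y <- rnorm(2000)
  d2 <- rbind(data.frame(gene_id = g2, attribute = "length", delta = x),
              data.frame(gene_id = g2, attribute = "tss_bin", delta = y))
  expect_lt(abs(delta_correlations(d2)$rho["length", "tss_bin"]), 0.06)

  d3 <- rbind(data.frame(gene_id = g2, attribute = "length", delta = x),
              data.frame(gene_id = g2, attribute = "pas_bin",
                         delta = x + rnorm(2000, sd = 0.05)))
  expect_gt(delta_correlations(d3)$rho["length", "pas_bin"], 0.9)

  ## fewer than 3 genes: flagged undefined
  d4 <- d[d$gene_id %in% g[1:2], ]
  expect_true(is.na(delta_correlations(d4)$rho["length", "pas_bin"]))
})

test_that("catalog attribute table bins within genes and flags coding", {
  fx <- tiny_sim()
  attrs <- isoform_attributes(fx$catalog)
  expect_true(all(attrs$tss_bin >= 0))
  expect_true(all(attrs$pas_bin >= 0))
  ## every multi-isoform gene anchors one isoform at bin 0 for each site type
  for (ix in split(seq_len(nrow(attrs)), attrs$gene_id)) {
    expect_equal(min(attrs$tss_bin[ix]), 0)
    expect_equal(min(attrs$pas_bin[ix]), 0)
  }
  expect_setequal(unique(attrs$coding_score), c(1, -1))
})
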