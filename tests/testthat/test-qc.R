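test_that("barcode filter applies the gene-count, mito and percentile rules exactly", {
  ## 150 ordinary genes + 1 mitochondrial gene, one isoform each
  cat_ <- toy_catalog(c(sprintf("G%03d", 1:150), "mt-1"))
  n_bc <- 4
  cells <- toy_cells(n_bc)
  m <- matrix(0, n_bc, nrow(cat_), dimnames = list(cells$barcode, cat_$isoform_id))
  m[1, 1:99] <- 1                      # 99 genes -> removed (fewer than 100)
  m[2, 1:100] <- 1                     # exactly 100 -> kept
  m[3, 1:100] <- 1; m[3, 151] <- 34    # 101 genes, mito 34/134 ~ 0.254 -> removed
  m[4, 1:110] <- 1; m[4, 151] <- 2     # mito ~ 0.018 -> kept
  res <- filter_barcodes(as(m, "CsparseMatrix"), cells, cat_)
  expect_setequal(rownames(res$counts), cells$barcode[c(2, 4)])
  expect_equal(res$cells$n_genes_detected, c(100L, 111L))
  expect_equal(res$cells$mito_fraction[2], 2 / 112, tolerance = 1e-12)
})

test_that("the 98th-percentile rule removes exactly the strictly-greater barcodes", {
  n <- 1000
  genes <- sprintf("G%04d", seq_len(n))
  cat_ <- toy_catalog(genes)
  cells <- toy_cells(n)
  ## barcode i detects exactly i genes: lower-triangular indicator
  tri <- Matrix::sparseMatrix(
    i = unlist(lapply(seq_len(n), function(i) rep(i, i))),
    j = unlist(lapply(seq_len(n), function(i) seq_len(i))),
    x = 1, dims = c(n, n), dimnames = list(cells$barcode, cat_$isoform_id))
  res <- filter_barcodes(tri, cells, cat_, min_genes = 1)
  ## threshold = 980th order statistic; the 20 barcodes above it are removed
  expect_equal(nrow(res$counts), 980)
  expect_equal(max(res$cells$n_genes_detected), 980L)
})

test_that("transcript filter enforces TSL and per-stratum prevalence", {
  genes <- c("G1", "G1", "G2", "G3")
  iso <- c("G1-201", "G1-202", "G2-201", "G3-201")
  cat_ <- toy_catalog(genes, iso, tsl = c(1L, 2L, 1L, 1L))
  n <- 300
  cells <- toy_cells(n)
  m <- matrix(0, n, 4, dimnames = list(cells$barcode, iso))
  m[1:50, 1] <- 5     # prevalent, TSL1 -> kept
  m[1:50, 2] <- 5     # prevalent but TSL2 -> removed
  m[1, 3] <- 1        # 1/300 = 0.33% -> removed
  m[1:2, 4] <- 1      # 2/300 = 0.67% -> kept
  kept <- filter_transcripts(as(m, "CsparseMatrix"), cat_, cells)
  expect_setequal(colnames(kept), c("G1-201", "G3-201"))

  ## prevalence is assessed within (cell type x sex x region) strata:
  ## the same 2 positive cells among 300 now sit in a 100-cell stratum (2%)
  cells2 <- toy_cells(n, cell_type = rep(c("neuron", "immune", "oligo"), each = 100))
  m2 <- matrix(0, n, 4, dimnames = list(cells2$barcode, iso))
  m2[1, 3] <- 1
  kept2 <- filter_transcripts(as(m2, "CsparseMatrix"), cat_, cells2,
                              min_cell_frac = 0.01)
  expect_true("G2-201" %in% colnames(kept2))
})

test_that("pseudobulk sums counts per unit and conserves mass", {
  cat_ <- toy_catalog("G1")
  cells <- toy_cells(3, cell_type = c("neuron", "neuron", "immune"))
  m <- matrix(c(3, 4, 5), 3, 1, dimnames = list(cells$barcode, cat_$isoform_id))
  pb <- pseudobulk(as(m, "CsparseMatrix"), cells)
  expect_equal(unname(pb$counts[paste0("S01|neuron"), 1]), 7)
  expect_equal(unname(pb$counts[paste0("S01|immune"), 1]), 5)
  expect_equal(sum(pb$counts), sum(m))
  expect_equal(nrow(pb$counts), 2)   # units with zero cells omitted
  expect_equal(pb$units$n_cells[match("S01|neuron", rownames(pb$units))], 2L)
})

test_that("size factors match the closed form and a brute-force oracle", {
  m <- rbind(c(2, 4), c(4, 8))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  expect_equal(unname(size_factors(rbind(c(3, 7), c(3, 7)))), c(1, 1))

  set.seed(1)
  m2 <- matrix(rpois(300, 50) + 1, 50, 6)
  ## independent brute-force median-of-ratios (per-isoform geometric means)
  geo <- vapply(seq_len(ncol(m2)), function(j) prod(m2[, j])^(1 / nrow(m2)),
                numeric(1))
  oracle <- apply(m2, 1, function(row) median(row / geo))
  expect_equal(unname(size_factors(m2)), unname(oracle), tolerance = 1e-12)

  ## scale equivariance: scaling one of n units scales its factor by
  ## c^((n-1)/n), the geometric-mean reference absorbing the remaining c^(1/n)
  m3 <- m2; m3[1, ] <- m3[1, ] * 5
  expect_equal(unname(size_factors(m3)[1]),
               unname(size_factors(m2)[1] * 5^(49 / 50)), tolerance = 1e-9)

  expect_error(size_factors(rbind(c(0, 2), c(1, 0))), "gene level")
})

test_that("usage is the within-gene count ratio, NA on zero totals", {
  cat_ <- toy_catalog(c("G1", "G1", "G2"), c("G1-201", "G1-202", "G2-201"))
  m <- rbind(u1 = c(30, 10, 0), u2 = c(0, 0, 5))
  colnames(m) <- cat_$isoform_id
  u <- isoform_usage(m, cat_)
  expect_equal(unname(u["u1", 1:2]), c(0.75, 0.25))
  expect_true(is.na(u["u1", 3]))
  expect_equal(unname(u["u2", 3]), 1)  # single-isoform gene
  ## scale invariance per unit
  m2 <- m; m2["u1", ] <- m2["u1", ] * 10
  expect_equal(isoform_usage(m2, cat_), u)
})

test_that("QC outputs are invariant to barcode order", {
  fx <- tiny_sim()
  perm <- sample(nrow(fx$counts))
  a <- filter_barcodes(fx$counts, fx$cells, fx$catalog)
  cells_p <- fx$cells[perm, ]
  b <- filter_barcodes(fx$counts[perm, ], cells_p, fx$catalog)
  expect_setequal(rownames(a$counts), rownames(b$counts))
  ka <- filter_transcripts(a$counts, fx$catalog, a$cells)
  kb <- filter_transcripts(b$counts, fx$catalog, b$cells)
  expect_setequal(colnames(ka), colnames(kb))
})
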