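test_that("generator is deterministic under a fixed seed and robust to call order", {
  cfg <- simulation_config(n_genes = 50, n_cells_per_sample = 30, seed = 7)
  cat_a <- generate_catalog(cfg)
  cells_a <- generate_cells(cfg)
  sim_a <- simulate_counts(cat_a, cells_a, cfg)
  ## different call order: counts drawn before a second catalog
  cat_b <- generate_catalog(cfg)
  sim_b <- simulate_counts(cat_b, generate_cells(cfg), cfg)
  expect_identical(as.data.frame(cat_a), as.data.frame(cat_b))
  expect_identical(sim_a$counts, sim_b$counts)
  expect_identical(sim_a$truth$cig_genes, sim_b$truth$cig_genes)
})

test_that("catalog respects the configured isoform-count range and structure", {
  cfg1 <- simulation_config(n_genes = 30, isoforms_per_gene = c(1, 1),
                            n_marker_genes = 0, n_mt_genes = 0, seed = 1)
  cat1 <- generate_catalog(cfg1)
  expect_true(all(table(cat1$gene_id) == 1))

  cfg <- simulation_config(n_genes = 500, isoforms_per_gene = c(1, 4),
                           n_marker_genes = 0, n_mt_genes = 0, seed = 1)
  cat_ <- generate_catalog(cfg)
  ## empirical isoform-count histogram vs the uniform sampling distribution
  tab <- table(factor(table(cat_$gene_id), levels = 1:4))
  expect_gt(stats::chisq.test(tab, p = rep(0.25, 4))$p.value, 0.01)

  ## within-gene structural invariants
  by_gene <- split(seq_len(nrow(cat_)), cat_$gene_id)
  for (ix in by_gene[lengths(by_gene) > 1]) {
    expect_length(unique(cat_$chrom[ix]), 1)
    expect_length(unique(cat_$strand[ix]), 1)
    expect_false(anyDuplicated(cat_$tss[ix]) > 0)
    expect_false(anyDuplicated(cat_$pas[ix]) > 0)
  }
  expect_true(all(cat_$length > 0))
  expect_true(all(cat_$exon_count >= 1))
  coding <- !is.na(cat_$cds_length)
  expect_equal(cat_$utr5_length[coding] + cat_$cds_length[coding] +
                 cat_$utr3_length[coding], cat_$length[coding])
})

test_that("generated cells follow the design, proportions and senescence rules", {
  fx <- tiny_sim()
  cells <- fx$cells
  expect_equal(nrow(cells), nrow(fx$config$design) * fx$config$n_cells_per_sample)
  expect_false(anyDuplicated(cells$barcode) > 0)
  expect_true(all(cells$barcode[cells$senescent] %in%
                    cells$barcode[cells$cell_type == "immune"]))
  expect_false(any(cells$senescent[cells$age_category == "young"]))

  cfg0 <- simulation_config(n_genes = 30, n_cells_per_sample = 30,
                            senescent_fraction = 0, seed = 3)
  expect_false(any(generate_cells(cfg0)$senescent))

  ## binomial check on proportions at n = 10,000
  cfg2 <- simulation_config(
    n_genes = 30, n_cells_per_sample = 2500,
    cell_type_proportions = c(neuron = 0.5, immune = 0.5), seed = 5)
  cells2 <- generate_cells(cfg2)
  expect_equal(mean(cells2$cell_type == "neuron"), 0.5, tolerance = 0.04)
})

test_that("planted cell-type usage shifts have the configured magnitude", {
  cfg <- simulation_config(n_genes = 60, n_cells_per_sample = 150,
                           isoforms_per_gene = c(2, 3), cig_fraction = 0.3,
                           aig_fraction = 0, usage_effect_size = 0.4,
                           n_marker_genes = 0, seed = 21)
  catalog <- generate_catalog(cfg)
  cells <- generate_cells(cfg)
  sim <- simulate_counts(catalog, cells, cfg)
  m <- as.matrix(sim$counts)
  diffs <- vapply(seq_len(nrow(sim$truth$cig_genes)), function(i) {
    gid <- sim$truth$cig_genes$gene_id[i]
    ct <- sim$truth$cig_genes$cell_type[i]
    tgt <- sim$truth$cig_genes$target_isoform[i]
    cols <- which(catalog$gene_id == gid)
    in_ct <- cells$cell_type == ct
    u_in <- sum(m[in_ct, match(tgt, catalog$isoform_id)]) /
      sum(m[in_ct, cols])
    u_out <- sum(m[!in_ct, match(tgt, catalog$isoform_id)]) /
      sum(m[!in_ct, cols])
    u_in - u_out
  }, numeric(1))
  expect_true(all(abs(diffs - 0.4) < 0.05))
})

test_that("a null generator produces no usage signal between cell types", {
  cfg <- simulation_config(n_genes = 200, n_cells_per_sample = 80,
                           cig_fraction = 0, aig_fraction = 0,
                           usage_effect_size = 0, n_marker_genes = 0,
                           senescent_fraction = 0, seed = 13)
  catalog <- generate_catalog(cfg)
  cells <- generate_cells(cfg)
  sim <- simulate_counts(catalog, cells, cfg)
  pb <- pseudobulk(sim$counts, cells)
  grp <- ifelse(pb$units$cell_type == "immune", "immune", "rest")
  scan <- run_usage_scan(pb, catalog, grp, focus = "immune")
  p <- scan$gene_table$p_value
  expect_lte(mean(p < 0.001, na.rm = TRUE), 0.005 + 0.006)
})

test_that("fixtures round-trip through the readers", {
  fx <- tiny_sim()
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx$catalog, fx$cells, fx$counts, fx$truth, dir)
  expect_true(all(file.exists(paths)))

  cm <- read_counts(paths["mtx"], paths["barcodes"], paths["features"])
  expect_equal(as.matrix(cm), as.matrix(fx$counts))

  cat2 <- parse_gtf(paths["gtf"])
  key <- c("tss", "pas", "length", "exon_count", "coding", "tsl",
           "cds_length", "utr5_length", "utr3_length")
  m <- match(fx$catalog$isoform_id, cat2$isoform_id)
  expect_false(anyNA(m))
  for (col in key) {
    expect_equal(cat2[[col]][m], fx$catalog[[col]],
                 ignore_attr = TRUE, label = col)
  }

  cells2 <- read_cell_metadata(paths["cells"])
  expect_equal(cells2$barcode, fx$cells$barcode)
  expect_equal(cells2$sex, fx$cells$sex)

  markers <- readLines(paths["markers"])
  expect_setequal(markers, fx$truth$marker_genes)
})

test_that("an empty count matrix round-trips", {
  cat_ <- toy_catalog(c("G1", "G2"))
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(2, 2),
                            dimnames = list(c("B1", "B2"), cat_$isoform_id))
  dir <- withr::local_tempdir()
  Matrix::writeMM(as(m, "generalMatrix"), file.path(dir, "m.mtx"))
  writeLines(rownames(m), file.path(dir, "b.tsv"))
  writeLines(colnames(m), file.path(dir, "f.tsv"))
  m2 <- read_counts(file.path(dir, "m.mtx"), file.path(dir, "b.tsv"),
                    file.path(dir, "f.tsv"))
  expect_equal(sum(m2), 0)
  expect_equal(dim(m2), c(2L, 2L))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(design = default_design()[0, ]), "at least one")
  expect_error(simulation_config(usage_effect_size = 0.7), "0.5")
  expect_error(simulation_config(
    cell_type_proportions = c(neuron = 0.5, immune = 0.4)), "sum to 1")
})
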