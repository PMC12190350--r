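test_that("senescence scores follow the 10k normalization and thresholds", {
  ## 20 marker genes with one isoform each + filler gene
  markers <- sprintf("Sen%02d", 1:20)
  cat_ <- toy_catalog(c(markers, "G1"))
  cells <- toy_cells(4, cell_type = "immune",
                     age_months = c(4, 4, 27, 27))
  m <- matrix(0, 4, 21, dimnames = list(cells$barcode, cat_$isoform_id))
  ## cell 1 (young): total 10,000 with marker counts (10, 0, ..., 0)
  m[1, 1] <- 10; m[1, 21] <- 9990
  ## cell 2 (young): same profile, different depth (raw score is depth-free)
  m[2, ] <- m[1, ] * 3
  ## cell 3 (aged): marker expression 5.1x the young mean share
  m[3, 1] <- 51; m[3, 21] <- 9949
  ## cell 4 (aged): low marker share
  m[4, 1] <- 2; m[4, 21] <- 9998
  sc <- senescence_score(as(m, "CsparseMatrix"), cells, markers, cat_)
  expect_equal(sc$raw_score[1], 0.5)
  expect_equal(sc$raw_score[2], 0.5)   # depth invariance
  expect_equal(sc$norm_score[3], 5.1, tolerance = 1e-9)
  expect_equal(sc$label[3], "senescent")
  expect_equal(sc$label[4], "non-senescent")
  ## young mean normalized score is exactly 1 per cell type
  expect_equal(mean(sc$norm_score[cells$age_category == "young"]), 1,
               tolerance = 1e-12)
})

test_that("ml labels use strict 4/7 boundaries", {
  markers <- "Sen01"
  cat_ <- toy_catalog(c(markers, "G1"))
  norm_targets <- c(1, 3.9, 5.5, 7.1, 4, 7)
  n <- length(norm_targets) + 1
  cells <- toy_cells(n, cell_type = "immune", age_months = c(4, rep(27, n - 1)))
  m <- matrix(0, n, 2, dimnames = list(cells$barcode, cat_$isoform_id))
  m[1, 1] <- 10; m[1, 2] <- 9990          # young reference: raw 5
  for (i in seq_along(norm_targets)) {
    m[i + 1, 1] <- round(10 * norm_targets[i])
    m[i + 1, 2] <- 10000 - m[i + 1, 1]
  }
  sc <- senescence_score(as(m, "CsparseMatrix"), cells, markers, cat_)
  expect_equal(sc$ml_label[2:7], c(0L, 0L, NA, 1L, NA, NA))
  expect_equal(sc$label[2:7], c("non-senescent", "non-senescent",
                                "senescent", "senescent",
                                "non-senescent", "senescent"))
})

test_that("planted senescent cells are recovered with high precision and recall", {
  fx <- tiny_sim()
  sc <- senescence_score(fx$counts, fx$cells, fx$truth$marker_genes, fx$catalog)
  truth <- fx$cells$senescent
  pred <- !is.na(sc$label) & sc$label == "senescent"
  expect_gte(sum(pred & truth) / sum(pred), 0.9)
  expect_gte(sum(pred & truth) / sum(truth), 0.9)
  ## young-cell mean normalized score is 1 within each cell type
  young <- fx$cells$age_category == "young"
  ym <- tapply(sc$norm_score[young], fx$cells$cell_type[young], mean)
  expect_true(all(abs(ym - 1) < 1e-9))
  ## proportions invariant to barcode order
  p1 <- senescence_proportions(sc, fx$cells)
  perm <- sample(nrow(fx$cells))
  sc2 <- sc[perm, ]; cl2 <- fx$cells[perm, ]
  p2 <- senescence_proportions(sc2, cl2)
  m <- merge(p1, p2, by = c("cell_type", "age_category", "sex", "region"))
  expect_equal(m$fraction.x, m$fraction.y)
})

test_that("marker discovery recovers planted senescence-coupled usage switches", {
  fx <- sen_sim()
  sc <- senescence_score(fx$counts, fx$cells, fx$truth$marker_genes, fx$catalog)
  disc <- discover_markers(fx$counts, fx$cells, sc, fx$catalog)
  expect_gte(length(intersect(disc$genes, fx$truth$marker_genes)), 15)
  ## discovered genes are a subset of the tested genes
  tested <- disc$scan$gene_table$gene_id[!is.na(disc$scan$gene_table$p_value)]
  expect_true(all(disc$genes %in% tested))
  ## insufficient senescent cells is an explicit error
  few <- fx$cells$senescent & duplicated(fx$cells$senescent)  # none
  sc_few <- sc; sc_few$label[sc$label == "senescent"] <- "non-senescent"
  expect_error(discover_markers(fx$counts, fx$cells, sc_few, fx$catalog),
               ">=")
})

test_that("usage PCA separates planted groups and handles degenerate input", {
  set.seed(14)
  X <- cbind(c(rnorm(50, -3, 0.1), rnorm(50, 3, 0.1)), rnorm(100, 0, 0.1))
  colnames(X) <- c("F1", "F2")
  res <- usage_pca(X)
  pc1 <- res$scores[, 1]
  expect_true(max(pc1[1:50]) < min(pc1[51:100]) ||
                min(pc1[1:50]) > max(pc1[51:100]))
  expect_lte(sum(res$explained), 1 + 1e-12)

  ## identical cells: zero scores
  res0 <- usage_pca(matrix(0.5, 10, 3))
  expect_true(all(res0$scores == 0))

  ## missing usages are mean-imputed
  X2 <- X; X2[1, 1] <- NA
  expect_silent(usage_pca(X2))
})

test_that("the classifier is exact on separable data and chance on permuted labels", {
  set.seed(15)
  X <- matrix(rnorm(2000 * 5), 2000, 5)
  colnames(X) <- paste0("F", 1:5)
  y <- as.integer(X[, 1] > 0)
  clf <- train_classifier(X, y, seed = 2)
  expect_equal(clf$auroc, 1.0)
  ## deterministic at fixed seed
  clf2 <- train_classifier(X, y, seed = 2)
  expect_identical(predict_scores(clf, X), predict_scores(clf2, X))
  ## split proportions and exhaustiveness
  expect_equal(sum(table(clf$split)), 2000)
  expect_gt(mean(clf$split == "train"), 0.85)
  ## ROC cross-check against an independent implementation
  pr <- clf$test_predictions
  expect_equal(as.numeric(suppressMessages(pROC::auc(pr$label, pr$prob))),
               clf$auroc, tolerance = 1e-9)

  y_perm <- sample(y)
  clf3 <- train_classifier(X, y_perm, seed = 2)
  expect_gt(clf3$auroc, 0.3)
  expect_lt(clf3$auroc, 0.7)
})

test_that("prediction validates the feature manifest and imputes missing rows", {
  set.seed(16)
  X <- matrix(rnorm(500 * 4), 500, 4)
  colnames(X) <- paste0("F", 1:4)
  y <- as.integer(X[, 2] > 0)
  clf <- train_classifier(X, y, seed = 3)
  expect_error(predict_scores(clf, X[, 1:3]), "F4")
  Xna <- X; Xna[1, ] <- NA
  expect_warning(p <- predict_scores(clf, Xna), "no observed")
  expect_true(all(p >= 0 & p <= 1))
})
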