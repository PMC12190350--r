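#' Cell-level senescence scores
#'
#' Scales each cell's counts to a total of 10,000, takes the mean scaled
#' expression over all isoforms of the marker genes (raw score), and divides
#' by the mean raw score of the young cells of the same cell type (normalized
#' score). Cells are labeled senescent when the normalized score is strictly
#' above `sen_threshold`; machine-learning labels are 0 strictly below
#' `ml_low`, 1 strictly above `ml_high`, and excluded (NA) in between or on
#' the boundaries.
#'
#' @param counts barcodes x isoforms matrix.
#' @param cells matching `cell_table` (needs cell_type and age_category).
#' @param markers character vector of marker gene ids.
#' @param catalog isoform catalog resolving genes to isoforms.
#' @param target_sum per-cell count normalization total (default 10000).
#' @param sen_threshold,ml_low,ml_high labeling thresholds (defaults 5, 4, 7).
#' @param mode `"isoform_mean"` (default) averages scaled counts over all
#'   marker isoforms; `"gene_mean"` first sums isoforms within each marker
#'   gene and then averages over genes.
#' @return data.frame of class `senescence_scores` keyed by barcode with
#'   raw_score, norm_score, label, ml_label. Cells of a type with no young
#'   cells (or zero young mean) get NA scores with the reason recorded in
#'   the `excluded_types` attribute.
#' @export
senescence_score <- function(counts, cells, markers, catalog,
                             target_sum = 1e4, sen_threshold = 5,
                             ml_low = 4, ml_high = 7,
                             mode = c("isoform_mean", "gene_mean")) {
  mode <- match.arg(mode)
  stopifnot(nrow(counts) == nrow(cells))
  gene_of <- catalog$gene_id[match(colnames(counts), catalog$isoform_id)]
  missing_markers <- setdiff(markers, gene_of)
  if (length(missing_markers)) {
    stopf("marker gene(s) with no isoform in the matrix: %s",
          paste(missing_markers, collapse = ", "))
  }
  marker_cols <- which(gene_of %in% markers)
  totals <- Matrix::rowSums(counts)
  scl <- ifelse(totals > 0, target_sum / totals, 0)
  scaled <- Matrix::Diagonal(x = scl) %*% counts[, marker_cols, drop = FALSE]
  raw <- if (mode == "isoform_mean") {
    Matrix::rowSums(scaled) / length(marker_cols)
  } else {
    g <- gene_of[marker_cols]
    gm <- vapply(unique(g), function(gg) {
      Matrix::rowSums(scaled[, g == gg, drop = FALSE])
    }, numeric(nrow(scaled)))
    rowMeans(gm)
  }
  young_mean <- tapply(raw[cells$age_category == "young"],
                       cells$cell_type[cells$age_category == "young"], mean)
  denom <- young_mean[cells$cell_type]
  norm <- as.numeric(raw / denom)
  excluded_types <- union(
    setdiff(unique(cells$cell_type), names(young_mean)),
    names(young_mean)[!is.na(young_mean) & young_mean == 0])
  norm[cells$cell_type %in% excluded_types] <- NA_real_
  out <- data.frame(
    barcode = cells$barcode,
    cell_type = cells$cell_type,
    raw_score = as.numeric(raw),
    norm_score = norm,
    label = ifelse(is.na(norm), NA_character_,
                   ifelse(norm > sen_threshold, "senescent", "non-senescent")),
    ml_label = ifelse(is.na(norm), NA_integer_,
                      ifelse(norm < ml_low, 0L,
                             ifelse(norm > ml_high, 1L, NA_integer_))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$barcode
  attr(out, "excluded_types") <- excluded_types
  class(out) <- c("senescence_scores", "data.frame")
  out
}

#' Senescent-cell proportions per stratum
#'
#' @param scores `senescence_scores`.
#' @param cells matching `cell_table`.
#' @param by stratifying columns (default cell type x age category x sex x
#'   region).
#' @return data.frame with the strata, labeled-cell counts, senescent counts
#'   and fractions; empty strata are omitted.
#' @export
senescence_proportions <- function(scores, cells,
                                   by = c("cell_type", "age_category", "sex",
                                          "region")) {
  stopifnot(identical(scores$barcode, cells$barcode))
  ok <- !is.na(scores$label)
  df <- cbind(cells[ok, by, drop = FALSE],
              senescent = scores$label[ok] == "senescent")
  agg <- aggregate(senescent ~ ., data = df, FUN = function(x) c(sum(x), length(x)))
  out <- agg[setdiff(names(agg), "senescent")]
  out$n_senescent <- agg$senescent[, 1]
  out$n_labeled <- agg$senescent[, 2]
  out$fraction <- out$n_senescent / out$n_labeled
  out
}

#' Discover senescence marker genes by differential isoform usage
#'
#' Builds sample x senescence-label pseudobulk units within immune cells
#' (all timepoints pooled) and scans for genes whose isoform usage differs
#' between senescent and non-senescent cells, keeping genes at BH-adjusted
#' p below `padj_threshold`.
#'
#' @param counts barcodes x isoforms matrix (QC- and transcript-filtered).
#' @param cells matching `cell_table`.
#' @param scores `senescence_scores` for the same barcodes.
#' @param catalog isoform catalog.
#' @param padj_threshold adjusted-p threshold (default 0.01).
#' @param min_cells_per_group minimum senescent and non-senescent immune
#'   cells required (default 20).
#' @return list with `genes`, `isoforms` (of those genes, with feature-level
#'   results) and the underlying `scan`.
#' @export
discover_markers <- function(counts, cells, scores, catalog,
                             padj_threshold = 0.01, min_cells_per_group = 20) {
  stopifnot(identical(rownames(counts), cells$barcode),
            identical(scores$barcode, cells$barcode))
  imm <- cells$cell_type == "immune" & !is.na(scores$label)
  n_sen <- sum(imm & scores$label == "senescent")
  n_non <- sum(imm & scores$label == "non-senescent")
  if (n_sen < min_cells_per_group || n_non < min_cells_per_group) {
    stopf("need >= %d immune cells per senescence state (got %d senescent, %d non-senescent)",
          min_cells_per_group, n_sen, n_non)
  }
  sub_cells <- cells[imm, , drop = FALSE]
  sub_cells$sen_label <- scores$label[imm]
  pb <- pseudobulk(counts[imm, , drop = FALSE], sub_cells,
                   keys = c("sample_id", "sen_label"))
  if (min(table(pb$units$sen_label)) < 2) {
    stopf("need >= 2 pseudobulk units per senescence state")
  }
  scan <- run_usage_scan(pb, catalog, groups = pb$units$sen_label,
                         focus = "senescent", alpha = padj_threshold,
                         use_adjusted = TRUE)
  genes <- scan$significant_genes
  iso <- scan$isoform_table[scan$isoform_table$gene_id %in% genes, , drop = FALSE]
  list(genes = genes, isoforms = iso, scan = scan)
}

#' Per-cell isoform usage features for marker genes
#'
#' Usage of each isoform of the requested genes within each cell (count over
#' the cell's gene total); `NA` where the gene total is zero, left missing
#' for the tree learner to handle natively.
#'
#' @param counts barcodes x isoforms matrix.
#' @param catalog isoform catalog.
#' @param genes genes whose isoforms become features.
#' @return dense cells x features matrix with NAs.
#' @export
cell_usage_features <- function(counts, catalog, genes) {
  gene_of <- catalog$gene_id[match(colnames(counts), catalog$isoform_id)]
  cols <- which(gene_of %in% genes)
  if (length(cols) < 1) stopf("no isoforms found for the requested genes")
  sub <- as.matrix(counts[, cols, drop = FALSE])
  g <- gene_of[cols]
  out <- matrix(NA_real_, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  for (gg in unique(g)) {
    jx <- which(g == gg)
    tot <- rowSums(sub[, jx, drop = FALSE])
    u <- sub[, jx, drop = FALSE] / tot
    u[tot == 0, ] <- NA_real_
    out[, jx] <- u
  }
  out
}

#' Principal components of marker isoform usage
#'
#' Mean-imputes missing usages per feature, drops all-missing or constant
#' features (flagged), and returns the first two principal-component scores
#' with explained-variance fractions.
#'
#' @param features cells x features usage matrix (NAs allowed).
#' @return list with `scores` (cells x 2), `explained` (length-2 fractions),
#'   `dropped_features`.
#' @export
usage_pca <- function(features) {
  stopifnot(ncol(features) >= 2)
  keep <- colSums(!is.na(features)) > 0
  X <- features[, keep, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    mj <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mj
  }
  vars <- apply(X, 2, var)
  if (all(vars == 0)) {
    return(list(scores = matrix(0, nrow(X), 2,
                                dimnames = list(rownames(X), c("PC1", "PC2"))),
                explained = c(0, 0),
                dropped_features = colnames(features)[!keep]))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2) scores <- cbind(scores, 0)
  colnames(scores) <- c("PC1", "PC2")
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained = c(expl, 0, 0)[1:2],
       dropped_features = colnames(features)[!keep])
}

## stratified 90/5/5 split by largest-remainder apportionment within strata
stratified_split <- function(strata, split = c(0.9, 0.05, 0.05)) {
  stopifnot(abs(sum(split) - 1) < 1e-9)
  assignment <- integer(length(strata))
  for (s in unique(strata)) {
    ix <- sample(which(strata == s))
    n <- length(ix)
    base <- floor(split * n)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(split * n - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    assignment[ix] <- rep.int(1:3, base)
  }
  factor(assignment, levels = 1:3, labels = c("train", "validation", "test"))
}

#' Train the gradient-boosted senescence classifier
#'
#' Splits the labeled cells into train/validation/test (default 90/5/5)
#' stratified by label x age category x sex x region, trains gradient-boosted
#' trees (binary logistic objective, area under the precision-recall curve as
#' the early-stopping metric on the validation split), and evaluates the ROC
#' curve and its area on the held-out test split. Missing usage features are
#' handled natively by the learner.
#'
#' @param features cells x features usage matrix (NAs allowed).
#' @param labels 0/1 vector (NA rows are dropped).
#' @param strata stratification factor (default label alone when NULL).
#' @param split train/validation/test fractions.
#' @param params boosting hyperparameters; the defaults follow standard
#'   practice for this task (learning rate 0.01, max depth 7, minimum child
#'   weight 16, subsample 0.9967762267267729, per-split column subsample
#'   0.4100293732438932, L2 regularization 6.001086886655973, approximate
#'   tree method).
#' @param nrounds,early_stopping_rounds boosting rounds cap and patience.
#' @param seed integer seed (controls the split and the learner).
#' @return object of class `senescence_classifier` with the fitted model,
#'   feature manifest, split indices, test ROC curve and AUROC.
#' @export
train_classifier <- function(features, labels, strata = NULL,
                             split = c(0.9, 0.05, 0.05),
                             params = list(), nrounds = 10000,
                             early_stopping_rounds = 50, seed = 1L) {
  ok <- !is.na(labels)
  features <- features[ok, , drop = FALSE]
  labels <- as.integer(labels[ok])
  strata <- if (is.null(strata)) factor(labels) else droplevels(interaction(
    labels, strata[ok], drop = TRUE))
  defaults <- list(objective = "binary:logistic", eval_metric = "aucpr",
                   eta = 0.01, max_depth = 7, min_child_weight = 16,
                   subsample = 0.9967762267267729,
                   colsample_bynode = 0.4100293732438932,
                   lambda = 6.001086886655973,
                   tree_method = "approx", nthread = 1)
  params <- utils::modifyList(defaults, params)
  params$seed <- as.integer(seed)
  with_seed(seed, {
    part <- stratified_split(as.character(strata), split)
    for (p in levels(part)) {
      if (length(unique(labels[part == p])) < 2) {
        stopf("%s split lacks one of the classes; provide more labeled cells", p)
      }
    }
    dtrain <- xgboost::xgb.DMatrix(features[part == "train", , drop = FALSE],
                                   label = labels[part == "train"], missing = NA)
    dval <- xgboost::xgb.DMatrix(features[part == "validation", , drop = FALSE],
                                 label = labels[part == "validation"], missing = NA)
    bst <- xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                              evals = list(validation = dval),
                              early_stopping_rounds = early_stopping_rounds,
                              verbose = 0)
    test_x <- features[part == "test", , drop = FALSE]
    test_y <- labels[part == "test"]
    pred <- predict(bst, xgboost::xgb.DMatrix(test_x, missing = NA))
    roc <- roc_curve(test_y, pred)
    structure(list(
      model = bst, feature_names = colnames(features),
      params = params, split = part,
      test_predictions = data.frame(label = test_y, prob = pred),
      roc = roc$points, auroc = roc$auc,
      best_iteration = tryCatch(xgboost::xgb.attr(bst, "best_iteration"),
                                error = function(e) NA) %||% NA_integer_
    ), class = "senescence_classifier")
  })
}

#' @export
print.senescence_classifier <- function(x, ...) {
  cat(sprintf(
    "senescence classifier: %d features, best iteration %s, test AUROC %.3f\n",
    length(x$feature_names), x$best_iteration, x$auroc))
  print(table(split = x$split))
  invisible(x)
}

#' Predicted senescence probabilities
#'
#' @param model `senescence_classifier`.
#' @param features cells x features matrix with the model's feature columns
#'   (missing values allowed and handled as in training; an all-missing row
#'   triggers a warning but still yields a prediction).
#' @return numeric probabilities in [0, 1].
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "senescence_classifier"))
  missing_feats <- setdiff(model$feature_names, colnames(features))
  if (length(missing_feats)) {
    stopf("missing feature column(s): %s", paste(missing_feats, collapse = ", "))
  }
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  if (any(rowSums(!is.na(X)) == 0)) {
    warning("some rows have no observed features; predictions use learner defaults",
            call. = FALSE)
  }
  predict(model$model, xgboost::xgb.DMatrix(X, missing = NA))
}

#' @export
predict.senescence_classifier <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}
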