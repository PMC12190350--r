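#' Barcode x gene view of an isoform count matrix
#'
#' @param counts sparse barcodes x isoforms matrix.
#' @param catalog isoform catalog mapping isoforms to genes.
#' @return sparse barcodes x genes matrix of summed isoform counts.
#' @export
gene_view <- function(counts, catalog) {
  gene <- catalog$gene_id[match(colnames(counts), catalog$isoform_id)]
  if (anyNA(gene)) stopf("counts contain isoforms absent from the catalog")
  genes <- unique(gene)
  ind <- Matrix::sparseMatrix(i = seq_along(gene), j = match(gene, genes), x = 1,
                              dims = c(length(gene), length(genes)),
                              dimnames = list(colnames(counts), genes))
  counts %*% ind
}

#' Barcode quality-control filter
#'
#' Removes barcodes with fewer than `min_genes` detected genes or more than
#' `mito_max` mitochondrial content, then removes barcodes whose detected
#' gene count strictly exceeds the `top_pct` empirical percentile of the
#' remaining barcodes (likely doublets). The percentile threshold is the
#' `ceiling(top_pct * m)`-th order statistic of the post-filter set; removal
#' uses strict inequality. QC fields are written into the cell table.
#'
#' @param counts barcodes x isoforms sparse matrix.
#' @param cells `cell_table` with one row per barcode of `counts`.
#' @param catalog isoform catalog (for the gene view and `mt-` genes).
#' @param mito_max maximum mitochondrial count fraction (default 0.20).
#' @param min_genes minimum distinct detected genes (default 100).
#' @param top_pct percentile bounding detected genes from above (default 0.98).
#' @param mito_pattern regex identifying mitochondrial gene ids.
#' @return list with filtered `counts` and `cells` (QC columns filled).
#' @export
filter_barcodes <- function(counts, cells, catalog, mito_max = 0.20,
                            min_genes = 100, top_pct = 0.98,
                            mito_pattern = "^mt-") {
  stopifnot(nrow(counts) == nrow(cells),
            identical(rownames(counts), cells$barcode))
  gv <- gene_view(counts, catalog)
  n_genes <- Matrix::rowSums(gv > 0)
  total <- Matrix::rowSums(gv)
  mt_cols <- grepl(mito_pattern, colnames(gv))
  mito <- if (any(mt_cols)) {
    Matrix::rowSums(gv[, mt_cols, drop = FALSE]) / pmax(total, 1)
  } else rep(0, nrow(gv))
  cells$n_genes_detected <- as.integer(n_genes)
  cells$mito_fraction <- as.numeric(mito)

  pass1 <- n_genes >= min_genes & mito <= mito_max
  if (!any(pass1)) stopf("all barcodes filtered by the min-genes/mito rules")
  thr <- sort(n_genes[pass1])[ceiling(top_pct * sum(pass1))]
  keep <- pass1 & n_genes <= thr
  if (!any(keep)) stopf("all barcodes filtered")
  list(counts = counts[keep, , drop = FALSE],
       cells = structure(cells[keep, , drop = FALSE],
                         class = c("cell_table", "data.frame")))
}

#' Transcript filter: support level and per-stratum prevalence
#'
#' Keeps an isoform iff its transcript support level equals `tsl_required`
#' and, in at least one (cell type x sex x region) stratum, it is detected
#' (nonzero count) in at least `min_cell_frac` of that stratum's cells.
#'
#' @param counts QC-passed barcodes x isoforms matrix.
#' @param catalog isoform catalog (TSL column).
#' @param cells matching `cell_table`.
#' @param min_cell_frac prevalence threshold (default 0.005).
#' @param tsl_required required transcript support level (default 1).
#' @return the column-filtered count matrix.
#' @export
filter_transcripts <- function(counts, catalog, cells, min_cell_frac = 0.005,
                               tsl_required = 1) {
  stopifnot(nrow(counts) == nrow(cells))
  tsl <- catalog$tsl[match(colnames(counts), catalog$isoform_id)]
  tsl_ok <- !is.na(tsl) & tsl == tsl_required
  stratum <- interaction(cells$cell_type, cells$sex, cells$region, drop = TRUE)
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(cells)),
                              j = as.integer(stratum), x = 1,
                              dims = c(nrow(cells), nlevels(stratum)))
  det <- Matrix::t(counts > 0) %*% ind          # isoform x stratum detection counts
  n_stratum <- Matrix::colSums(ind)
  prev <- sweep(as.matrix(det), 2, n_stratum, "/")
  prev_ok <- apply(prev, 1, max) >= min_cell_frac
  counts[, tsl_ok & prev_ok, drop = FALSE]
}

#' Pseudobulk aggregation
#'
#' Sums UMI counts over the barcodes of each unit, a unit being one
#' combination of the key columns (default sample x cell type). Units with
#' zero cells are omitted; total count mass is conserved.
#'
#' @param counts barcodes x isoforms matrix.
#' @param cells matching `cell_table`.
#' @param keys cell-table columns defining the units.
#' @return list of class `pseudobulk_matrix`: `counts` (dense units x
#'   isoforms matrix), `units` (data.frame of key columns plus carried
#'   sample covariates and `n_cells`).
#' @export
pseudobulk <- function(counts, cells, keys = c("sample_id", "cell_type")) {
  stopifnot(nrow(counts) == nrow(cells), all(keys %in% names(cells)))
  unit <- interaction(cells[keys], drop = TRUE, sep = "|")
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(cells)), j = as.integer(unit),
                              x = 1, dims = c(nrow(cells), nlevels(unit)))
  pb <- as.matrix(Matrix::t(Matrix::crossprod(counts, ind)))
  rownames(pb) <- levels(unit)
  colnames(pb) <- colnames(counts)
  units <- unique(cells[keys])
  units <- units[match(levels(unit), do.call(paste, c(units[keys], sep = "|"))), ,
                 drop = FALSE]
  carry <- setdiff(c("age_months", "age_category", "sex", "region"), keys)
  for (cv in carry) {
    if (cv %in% names(cells)) {
      units[[cv]] <- cells[[cv]][match(units$sample_id, cells$sample_id)]
    }
  }
  units$n_cells <- as.integer(table(unit)[levels(unit)])
  rownames(units) <- levels(unit)
  structure(list(counts = pb, units = units), class = "pseudobulk_matrix")
}

#' @export
print.pseudobulk_matrix <- function(x, ...) {
  cat(sprintf("pseudobulk matrix: %d units x %d isoforms (%.0f total counts)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' DESeq2-style normalization at the pseudobulk level: the reference is the
#' per-isoform geometric mean across units, computed over isoforms with
#' strictly positive counts in every unit; each unit's factor is the median
#' of its count/reference ratios.
#'
#' @param pb a `pseudobulk_matrix` or a plain units x isoforms count matrix.
#' @return positive numeric vector of per-unit size factors.
#' @export
size_factors <- function(pb) {
  m <- if (inherits(pb, "pseudobulk_matrix")) pb$counts else as.matrix(pb)
  pos <- colSums(m > 0) == nrow(m)
  if (!any(pos)) {
    stopf("no isoform has positive counts in every unit; aggregate to gene level for the reference")
  }
  sub <- m[, pos, drop = FALSE]
  geo <- exp(colMeans(log(sub)))
  ## median of natural-scale ratios (ties across an even reference set are
  ## averaged on the ratio scale, not the log scale)
  sf <- apply(sweep(sub, 2, geo, "/"), 1, median)
  setNames(sf, rownames(m))
}

#' Isoform usage per pseudobulk unit
#'
#' Usage is the ratio of an isoform's count to the summed counts of all
#' isoforms of its gene within the unit, computed on raw counts (usage is
#' scale-free); it is `NA` where the gene total is zero.
#'
#' @param pb a `pseudobulk_matrix` (or units x isoforms matrix).
#' @param catalog isoform catalog mapping isoforms to genes.
#' @return units x isoforms matrix of usages in [0, 1] or NA.
#' @export
isoform_usage <- function(pb, catalog) {
  m <- if (inherits(pb, "pseudobulk_matrix")) pb$counts else as.matrix(pb)
  gene <- catalog$gene_id[match(colnames(m), catalog$isoform_id)]
  if (anyNA(gene)) stopf("isoforms absent from the catalog")
  genes <- unique(gene)
  ind <- Matrix::sparseMatrix(i = match(gene, genes), j = seq_along(gene), x = 1,
                              dims = c(length(genes), length(gene)))
  gene_tot <- as.matrix(m %*% Matrix::t(ind))   # units x genes
  denom <- gene_tot[, match(gene, genes), drop = FALSE]
  u <- m / denom
  u[denom == 0] <- NA_real_
  dimnames(u) <- dimnames(m)
  u
}
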