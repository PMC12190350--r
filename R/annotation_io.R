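#' Parse a GTF annotation into an isoform catalog
#'
#' Reads an Ensembl-dialect GTF and derives, per transcript, the structural
#' attributes used downstream. All internal coordinates are 0-based; the TSS
#' is the 5'-most transcribed position in transcript orientation (minimum
#' exon start on `+`, maximum exon end minus one on `-`) and the PAS the
#' 3'-most position analogously. Transcript length is the sum of exon spans.
#' A transcript is coding iff `transcript_biotype == "protein_coding"`;
#' transcript support level is parsed when present (missing TSL is retained
#' as `NA` and only removed by the TSL filter). When CDS records are present,
#' the CDS length is their summed span and the 5'/3' UTR lengths are the
#' transcribed lengths up/downstream of the CDS in transcript orientation, so
#' `utr5 + cds + utr3 == length` exactly.
#'
#' @param path GTF file.
#' @return data.frame of class `isoform_catalog` (see [generate_catalog()]
#'   for the columns). Transcripts without exon records are dropped with a
#'   warning naming them.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(meta$type),
    stringsAsFactors = FALSE
  )
  df$transcript_id <- meta$transcript_id
  df$gene_id <- meta$gene_id
  df$biotype <- if ("transcript_biotype" %in% names(meta)) meta$transcript_biotype else NA
  df$tsl_raw <- if ("transcript_support_level" %in% names(meta)) {
    as.character(meta$transcript_support_level)
  } else NA_character_

  tx_meta <- df[df$type == "transcript" & !is.na(df$transcript_id), , drop = FALSE]
  if (nrow(tx_meta) == 0) {
    tx_meta <- df[df$type == "exon" & !is.na(df$transcript_id), , drop = FALSE]
    tx_meta <- tx_meta[!duplicated(tx_meta$transcript_id), , drop = FALSE]
  }
  exons <- df[df$type == "exon" & !is.na(df$transcript_id), , drop = FALSE]
  cds <- df[df$type == "CDS" & !is.na(df$transcript_id), , drop = FALSE]

  no_exons <- setdiff(tx_meta$transcript_id, exons$transcript_id)
  if (length(no_exons)) {
    warning(sprintf("dropping %d transcript(s) with no exon records: %s",
                    length(no_exons),
                    paste(head(no_exons, 5), collapse = ", ")), call. = FALSE)
    tx_meta <- tx_meta[!tx_meta$transcript_id %in% no_exons, , drop = FALSE]
  }

  ex_by_tx <- split(exons[, c("start", "end")], exons$transcript_id)
  cds_by_tx <- split(cds[, c("start", "end")], cds$transcript_id)

  rows <- lapply(seq_len(nrow(tx_meta)), function(r) {
    tid <- tx_meta$transcript_id[r]
    strand <- tx_meta$strand[r]
    ex <- ex_by_tx[[tid]]
    ex <- ex[order(ex$start), , drop = FALSE]
    len <- sum(ex$end - ex$start)
    if (strand == "+") {
      tss <- min(ex$start); pas <- max(ex$end) - 1L
    } else {
      tss <- max(ex$end) - 1L; pas <- min(ex$start)
    }
    tsl_raw <- tx_meta$tsl_raw[r]
    tsl <- suppressWarnings(as.integer(sub("^([0-9]+).*", "\\1", tsl_raw %||% NA)))
    cds_len <- utr5 <- utr3 <- NA_integer_
    cd <- cds_by_tx[[tid]]
    if (!is.null(cd) && nrow(cd)) {
      cds_len <- sum(cd$end - cd$start)
      if (strand == "+") {
        cds_5p <- min(cd$start)
        utr5 <- sum(pmax(0L, pmin(ex$end, cds_5p) - ex$start))
      } else {
        cds_5p <- max(cd$end)
        utr5 <- sum(pmax(0L, ex$end - pmax(ex$start, cds_5p)))
      }
      utr3 <- len - utr5 - cds_len
    }
    out <- data.frame(
      isoform_id = tid, gene_id = tx_meta$gene_id[r],
      chrom = tx_meta$chrom[r], strand = strand,
      tss = tss, pas = pas, length = len, exon_count = nrow(ex),
      coding = identical(tx_meta$biotype[r], "protein_coding"),
      tsl = tsl, cds_length = cds_len,
      utr5_length = utr5, utr3_length = utr3,
      stringsAsFactors = FALSE
    )
    out$exon_starts <- list(ex$start)
    out$exon_ends <- list(ex$end)
    out
  })
  cat <- do.call(rbind, rows)
  rownames(cat) <- cat$isoform_id
  class(cat) <- c("isoform_catalog", "data.frame")
  cat
}

#' Read a Matrix Market count matrix with barcode and feature axes
#'
#' @param mtx_path Matrix Market triplet file (barcodes x isoforms).
#' @param barcodes_path one barcode per line, in row order.
#' @param features_path TSV with isoform id (first column) and optionally
#'   gene id (second column), in column order.
#' @return sparse `dgCMatrix` (barcodes x isoforms) with dimnames; duplicate
#'   triplets are summed. If the features file carries gene ids they are
#'   attached as the `gene_ids` attribute.
#' @export
read_counts <- function(mtx_path, barcodes_path, features_path) {
  for (p in c(mtx_path, barcodes_path, features_path)) {
    if (!file.exists(p)) stopf("no such file: %s", p)
  }
  m <- Matrix::readMM(mtx_path)
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")  # sums duplicate triplets
  barcodes <- readLines(barcodes_path)
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(m) != length(barcodes)) {
    stopf("matrix has %d rows but %d barcodes listed", nrow(m), length(barcodes))
  }
  if (ncol(m) != nrow(feats)) {
    stopf("matrix has %d columns but %d features listed", ncol(m), nrow(feats))
  }
  dimnames(m) <- list(barcodes, feats[[1]])
  if (ncol(feats) >= 2) attr(m, "gene_ids") <- setNames(feats[[2]], feats[[1]])
  m
}

#' Read a cell-metadata table
#'
#' @param path TSV with header; requires columns barcode, sample_id,
#'   cell_type, age_months, age_category, sex, region. QC columns
#'   (`n_genes_detected`, `mito_fraction`) are optional and filled by
#'   [filter_barcodes()] when absent.
#' @return data.frame of class `cell_table`.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  # read everything as character first: a sex column of "F" would otherwise
  # be parsed as logical FALSE
  cells <- read.delim(path, colClasses = "character")
  numify <- function(col, fun) {
    if (col %in% names(cells)) cells[[col]] <<- suppressWarnings(fun(cells[[col]]))
  }
  numify("age_months", as.numeric)
  numify("n_genes_detected", as.integer)
  numify("mito_fraction", as.numeric)
  numify("senescent", as.logical)
  req <- c("barcode", "sample_id", "cell_type", "age_months", "age_category",
           "sex", "region")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols)) {
    stopf("metadata lacks required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cells$barcode)) stopf("duplicate barcodes in metadata")
  check_levels <- function(col, allowed) {
    bad <- which(!cells[[col]] %in% allowed)
    if (length(bad)) {
      stopf("invalid %s value '%s' in row %d", col, cells[[col]][bad[1]], bad[1])
    }
  }
  check_levels("cell_type", CELL_TYPES)
  check_levels("sex", SEXES)
  check_levels("region", REGIONS)
  check_levels("age_category", AGE_CATEGORIES)
  expected <- as.character(age_category_of(cells$age_months))
  bad <- which(cells$age_category != expected)
  if (length(bad)) {
    stopf("age_category '%s' inconsistent with age_months %s in row %d",
          cells$age_category[bad[1]], cells$age_months[bad[1]], bad[1])
  }
  if (!"n_genes_detected" %in% names(cells)) cells$n_genes_detected <- NA_integer_
  if (!"mito_fraction" %in% names(cells)) cells$mito_fraction <- NA_real_
  if (any(!is.na(cells$mito_fraction) &
          (cells$mito_fraction < 0 | cells$mito_fraction > 1))) {
    stopf("mito_fraction outside [0, 1]")
  }
  class(cells) <- c("cell_table", "data.frame")
  cells
}
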