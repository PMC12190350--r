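#' Bin genomic sites relative to the most upstream site
#'
#' Upstream is defined in transcription direction: the minimum coordinate on
#' the `+` strand and the maximum on `-`. The most upstream site gets bin 0
#' and every other site the floor of its distance from it divided by the bin
#' size (20 nt for TSSs, 75 nt for poly(A) sites by default elsewhere).
#'
#' @param sites genomic positions of one gene's sites.
#' @param strand `"+"` or `"-"`.
#' @param bin_size bin width in nucleotides.
#' @return integer bins, same length as `sites`.
#' @export
bin_positions <- function(sites, strand, bin_size) {
  stopifnot(length(sites) >= 1, strand %in% c("+", "-"), bin_size > 0)
  upstream <- if (strand == "+") min(sites) else max(sites)
  as.integer(floor(abs(sites - upstream) / bin_size))
}

#' Per-isoform attribute table
#'
#' Computes, for every isoform of the catalog, the attributes entering the
#' usage-weighted metric: transcript length, TSS and PAS bins (within-gene,
#' strand-aware, bin 0 = most upstream), exon count, coding score (+1 coding,
#' -1 non-coding), and CDS/UTR lengths where annotated.
#'
#' @param catalog isoform catalog.
#' @param tss_bin_size,pas_bin_size bin widths in nucleotides.
#' @return data.frame keyed by isoform_id with one column per attribute.
#' @export
isoform_attributes <- function(catalog, tss_bin_size = 20, pas_bin_size = 75) {
  out <- data.frame(
    isoform_id = catalog$isoform_id, gene_id = catalog$gene_id,
    length = catalog$length, exon_count = catalog$exon_count,
    coding_score = ifelse(catalog$coding, 1, -1),
    cds_length = catalog$cds_length, utr5_length = catalog$utr5_length,
    utr3_length = catalog$utr3_length,
    tss_bin = NA_integer_, pas_bin = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (ix in split(seq_len(nrow(catalog)), catalog$gene_id)) {
    strand <- catalog$strand[ix[1]]
    out$tss_bin[ix] <- bin_positions(catalog$tss[ix], strand, tss_bin_size)
    ## PAS: distances still measured from the most upstream PAS (transcription
    ## direction), so larger bins mean more downstream sites on either strand.
    out$pas_bin[ix] <- bin_positions(catalog$pas[ix], strand, pas_bin_size)
  }
  rownames(out) <- out$isoform_id
  out
}

#' Usage-weighted attribute metric of a gene
#'
#' `A_g = sum_i u_i * a_i` over the gene's isoforms, where `u` is the usage
#' simplex in one condition and `a` the attribute values. Returns `NA` when
#' any isoform with positive usage lacks the attribute (the gene is excluded
#' for that attribute) unless `renormalize` is set, in which case usage is
#' renormalized over the isoforms with a defined attribute (used for
#' CDS/UTR analyses restricted to coding isoforms).
#'
#' @param u usages, summing to 1 (tolerance 1e-6) over the gene's isoforms.
#' @param a attribute values, possibly with `NA`.
#' @param renormalize renormalize usage over defined isoforms.
#' @return the weighted attribute, or `NA`.
#' @export
weighted_attribute <- function(u, a, renormalize = FALSE) {
  stopifnot(length(u) == length(a))
  if (anyNA(u)) return(NA_real_)
  if (abs(sum(u) - 1) > 1e-6) stopf("usages must sum to 1 (got %.6g)", sum(u))
  ok <- !is.na(a)
  if (!any(ok)) return(NA_real_)
  if (!all(ok[u > 0])) {
    if (!renormalize) return(NA_real_)
    s <- sum(u[ok])
    if (s <= 0) return(NA_real_)
    return(sum(u[ok] * a[ok]) / s)
  }
  sum(u[ok] * a[ok])
}

#' Attribute delta between a condition and a reference
#'
#' The delta is `A_condition - A_reference`, except for the TSS bin where it
#' is negated so that a positive delta means a shift towards upstream TSSs.
#' Positive deltas therefore mean: longer isoform/CDS/UTRs, upstream TSS,
#' downstream PAS, higher coding potential. For one-vs-rest contrasts pass
#' the per-group usage matrix as `usage_ref`; the reference A is then the
#' unweighted mean of the other groups' A values.
#'
#' @param usage_cond usage vector of the gene in the condition.
#' @param usage_ref usage vector, or matrix (groups x isoforms) averaged
#'   after computing per-group A.
#' @param a attribute values per isoform.
#' @param attribute attribute name (the `"tss_bin"` delta is negated).
#' @param renormalize passed to [weighted_attribute()].
#' @return list with A_cond, A_ref, delta (NA when either side is undefined).
#' @export
attribute_delta <- function(usage_cond, usage_ref, a, attribute,
                            renormalize = FALSE) {
  A_cond <- weighted_attribute(usage_cond, a, renormalize)
  if (is.matrix(usage_ref)) {
    As <- apply(usage_ref, 1, weighted_attribute, a = a, renormalize = renormalize)
    A_ref <- mean(As[!is.na(As)])
    if (!length(As[!is.na(As)])) A_ref <- NA_real_
  } else {
    A_ref <- weighted_attribute(usage_ref, a, renormalize)
  }
  d <- A_cond - A_ref
  if (identical(attribute, "tss_bin")) d <- -d
  list(A_cond = A_cond, A_ref = A_ref, delta = d)
}

#' Per-gene attribute deltas for a scan's significant genes
#'
#' For each requested gene, computes the usage-weighted attribute in the
#' focus condition and in the reference (mean over the other groups), for
#' each attribute, from a units x isoforms usage matrix. Per-group usage is
#' the renormalized mean of the per-unit usage vectors over the group's
#' units with defined usage.
#'
#' @param usage units x isoforms usage matrix (from [isoform_usage()]).
#' @param groups group label per unit; `NA` units are ignored.
#' @param focus the condition group; all other groups form the reference.
#' @param attrs attribute table from [isoform_attributes()].
#' @param genes genes to evaluate (default: all genes in `attrs`).
#' @param attributes attribute columns to evaluate.
#' @return long data.frame: gene_id, attribute, A_cond, A_ref, delta.
#' @export
attribute_deltas <- function(usage, groups, focus, attrs,
                             genes = unique(attrs$gene_id),
                             attributes = c("length", "tss_bin", "pas_bin",
                                            "exon_count", "coding_score")) {
  groups <- as.character(groups)
  glev <- unique(groups[!is.na(groups)])
  stopifnot(focus %in% glev)
  renorm_attrs <- c("cds_length", "utr5_length", "utr3_length")
  rows <- list()
  for (gid in genes) {
    cols <- which(attrs$gene_id[match(colnames(usage), attrs$isoform_id)] == gid)
    if (length(cols) < 1) next
    a_tab <- attrs[match(colnames(usage)[cols], attrs$isoform_id), , drop = FALSE]
    group_usage <- function(g) {
      uu <- usage[which(groups == g), cols, drop = FALSE]
      uu <- uu[stats::complete.cases(uu), , drop = FALSE]
      if (nrow(uu) == 0) return(NULL)
      m <- colMeans(uu)
      m / sum(m)
    }
    u_focus <- group_usage(focus)
    if (is.null(u_focus)) next
    others <- setdiff(glev, focus)
    u_others <- lapply(others, group_usage)
    u_others <- u_others[!vapply(u_others, is.null, logical(1))]
    if (!length(u_others)) next
    ref_mat <- do.call(rbind, u_others)
    for (at in attributes) {
      d <- attribute_delta(u_focus, ref_mat, a_tab[[at]], at,
                           renormalize = at %in% renorm_attrs)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, attribute = at,
        A_cond = d$A_cond, A_ref = d$A_ref, delta = d$delta,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||% data.frame()
}

#' Classify which attributes change between a gene's top switching isoforms
#'
#' Picks the isoforms with the greatest increase and greatest decrease in
#' usage (feature-level effect sizes; ties broken by isoform id) and reports
#' the set of attributes on which the pair differs, among TSS, PAS, exon
#' count, length and coding potential.
#'
#' @param feature_results feature-level rows for one gene (columns `isoform`,
#'   `effect`).
#' @param attrs attribute table from [isoform_attributes()].
#' @return character vector (possibly empty) among
#'   `c("TSS", "PAS", "exon count", "length", "coding")`, or `NULL` when the
#'   gene has fewer than two testable isoforms.
#' @export
classify_pair_change <- function(feature_results, attrs) {
  if (is.null(feature_results) || nrow(feature_results) < 2) return(NULL)
  fr <- feature_results[order(feature_results$isoform), , drop = FALSE]
  up <- fr$isoform[which.max(fr$effect)]
  down <- fr$isoform[which.min(fr$effect)]
  if (up == down) return(NULL)
  a <- attrs[match(c(up, down), attrs$isoform_id), , drop = FALSE]
  labels <- c(tss_bin = "TSS", pas_bin = "PAS", exon_count = "exon count",
              length = "length", coding_score = "coding")
  changed <- vapply(names(labels), function(col) {
    a[[col]][1] != a[[col]][2]
  }, logical(1))
  unname(labels[changed])
}

#' Spearman correlations between attribute deltas across genes
#'
#' @param deltas long data.frame from [attribute_deltas()] (or any with
#'   gene_id, attribute, delta).
#' @param attributes attributes to correlate (default: all present).
#' @return list with `rho` (correlation matrix), `n` (pairwise sample
#'   sizes); pairs with fewer than 3 genes are `NA` and flagged in `n`.
#' @export
delta_correlations <- function(deltas, attributes = NULL) {
  attributes <- attributes %||% unique(deltas$attribute)
  wide <- do.call(cbind, lapply(attributes, function(at) {
    sub <- deltas[deltas$attribute == at, ]
    sub$delta[match(unique(deltas$gene_id), sub$gene_id)]
  }))
  colnames(wide) <- attributes
  n <- crossprod(!is.na(wide))
  rho <- suppressWarnings(cor(wide, method = "spearman",
                              use = "pairwise.complete.obs"))
  rho[n < 3] <- NA_real_
  list(rho = rho, n = n)
}
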