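#' Simulation configuration for the synthetic aging-brain isoform study
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults emulate one sex-region arm of a four-timepoint aging design
#' (young 4, middle 16, old 22, geriatric 27 months; three animals per
#' timepoint), five brain cell types, Dirichlet-multinomial isoform counts
#' with planted cell-type-specific usage genes (CIGs), age-dependent usage
#' genes (AIGs), quadratic temporal expression trajectories, and a senescent
#' immune subpopulation overexpressing marker genes.
#'
#' @param n_genes number of genes (including mitochondrial and marker genes).
#' @param isoforms_per_gene integer vector `c(min, max)`; isoform counts are
#'   drawn uniformly from `min:max`.
#' @param n_cells_per_sample cells contributed by each sample.
#' @param design data.frame with columns sample_id, age_months, age_category,
#'   sex, region; default three replicates at each of 4/16/22/27 months,
#'   female cortex.
#' @param cell_type_proportions named simplex over the five cell types.
#' @param cig_fraction,aig_fraction fractions of genes with planted
#'   cell-type-specific / age-dependent usage shifts.
#' @param usage_effect_size absolute usage shift (delta u) planted on the
#'   target isoform; must be < 0.5 so every baseline admits the shift.
#' @param trajectory_cluster_shapes list of quadratic coefficient triples
#'   (b0, b1, b2) on age scaled to [0, 1]; the expression multiplier of a gene
#'   assigned to shape k at scaled age s is `max(0.05, b0 + b1 s + b2 s^2)`.
#' @param senescent_fraction fraction of immune cells in non-young samples
#'   flagged senescent.
#' @param marker_fold expression multiplier of senescence marker genes in
#'   senescent cells.
#' @param n_marker_genes number of senescence marker genes (gene ids
#'   `Sen01`...); each has at least two isoforms and a senescence-coupled
#'   usage switch of size `usage_effect_size`.
#' @param marker_share total expression share of the marker genes; kept
#'   modest so the normalized senescence score of a senescent cell stays well
#'   above the labeling threshold (the score saturates as the share grows).
#' @param n_mt_genes,mt_share mitochondrial genes (prefix `mt-`) and their
#'   total expression share.
#' @param precision_gamma Dirichlet-multinomial concentration of per-cell
#'   isoform splits.
#' @param depth_mean expected UMIs per cell; per-cell depth factors are
#'   log-normal with unit mean and `depth_sd_log` log-sd.
#' @param depth_sd_log log-sd of the per-cell depth factor.
#' @param tsl1_prob probability an isoform is annotated at transcript support
#'   level 1 (others draw TSL 2-5).
#' @param coding_prob probability an isoform is protein coding.
#' @param seed integer master seed; each generator operation derives its own
#'   child seed from it, so outputs do not depend on call order.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 500,
                              isoforms_per_gene = c(min = 1, max = 4),
                              n_cells_per_sample = 170,
                              design = NULL,
                              cell_type_proportions = c(neuron = 0.35,
                                                        oligo = 0.25,
                                                        astrocyte = 0.15,
                                                        vascular = 0.10,
                                                        immune = 0.15),
                              cig_fraction = 0.10,
                              aig_fraction = 0.10,
                              usage_effect_size = 0.3,
                              trajectory_cluster_shapes = default_trajectory_shapes(),
                              senescent_fraction = 0.05,
                              marker_fold = 10,
                              n_marker_genes = 20,
                              marker_share = 0.02,
                              n_mt_genes = 5,
                              mt_share = 0.05,
                              precision_gamma = 30,
                              depth_mean = 2000,
                              depth_sd_log = 0.3,
                              tsl1_prob = 0.9,
                              coding_prob = 0.7,
                              seed = 1L) {
  if (is.null(design)) design <- default_design()
  if (length(n_genes) != 1 || is.na(n_genes) || n_genes < 1) {
    stopf("n_genes must be a positive count")
  }
  iso_min <- as.integer(isoforms_per_gene[[1]])
  iso_max <- as.integer(isoforms_per_gene[[length(isoforms_per_gene)]])
  if (iso_min < 1 || iso_max < iso_min) stopf("invalid isoforms_per_gene range")
  if (nrow(design) < 1) stopf("design must contain at least one sample")
  req <- c("sample_id", "age_months", "age_category", "sex", "region")
  if (!all(req %in% names(design))) {
    stopf("design lacks columns: %s", paste(setdiff(req, names(design)), collapse = ", "))
  }
  if (!all(design$age_category %in% AGE_CATEGORIES)) stopf("bad age_category in design")
  if (!all(design$sex %in% SEXES)) stopf("bad sex in design")
  if (!all(design$region %in% REGIONS)) stopf("bad region in design")
  if (abs(sum(cell_type_proportions) - 1) > 1e-9) {
    stopf("cell_type_proportions must sum to 1")
  }
  fracs <- c(cig_fraction, aig_fraction, senescent_fraction, tsl1_prob,
             coding_prob, marker_share, mt_share)
  if (any(fracs < 0 | fracs > 1)) stopf("fractions must lie in [0, 1]")
  if (usage_effect_size < 0 || usage_effect_size >= 0.5) {
    stopf("usage_effect_size must lie in [0, 0.5) so every baseline admits the shift")
  }
  if (precision_gamma <= 0 || depth_mean <= 0) stopf("precision_gamma and depth_mean must be positive")
  if (n_mt_genes + n_marker_genes >= n_genes) stopf("n_genes too small for mt + marker genes")
  structure(list(
    n_genes = as.integer(n_genes),
    isoforms_min = iso_min, isoforms_max = iso_max,
    n_cells_per_sample = as.integer(n_cells_per_sample),
    design = design,
    cell_type_proportions = cell_type_proportions,
    cig_fraction = cig_fraction, aig_fraction = aig_fraction,
    usage_effect_size = usage_effect_size,
    trajectory_cluster_shapes = trajectory_cluster_shapes,
    senescent_fraction = senescent_fraction,
    marker_fold = marker_fold,
    n_marker_genes = as.integer(n_marker_genes),
    marker_share = marker_share,
    n_mt_genes = as.integer(n_mt_genes), mt_share = mt_share,
    precision_gamma = precision_gamma,
    depth_mean = depth_mean, depth_sd_log = depth_sd_log,
    tsl1_prob = tsl1_prob, coding_prob = coding_prob,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_design <- function() {
  ages <- rep(c(4, 16, 22, 27), each = 3)
  data.frame(
    sample_id = sprintf("S%02d", seq_along(ages)),
    age_months = ages,
    age_category = as.character(age_category_of(ages)),
    sex = "F",
    region = "cortex",
    stringsAsFactors = FALSE
  )
}

# Eight temporal shapes spanning flat, monotone up/down, early/late and
# U-shaped responses, with geriatric/young fold changes from ~0.1 to 5.
#' @rdname simulation_config
#' @export
default_trajectory_shapes <- function() {
  list(
    c(1.0, 0.0, 0.0),
    c(1.0, -0.7, 0.0),
    c(1.0, 1.0, 0.0),
    c(1.0, 2.4, -2.0),
    c(1.0, -1.6, 1.2),
    c(0.4, 0.3, 1.3),
    c(1.6, -0.4, -1.0),
    c(1.0, 0.2, 0.6)
  )
}

trajectory_multiplier <- function(shape, age_months, age_range = c(4, 27)) {
  s <- (age_months - age_range[1]) / diff(age_range)
  pmax(0.05, shape[1] + shape[2] * s + shape[3] * s^2)
}

#' Generate a synthetic isoform catalog
#'
#' Places `n_genes` genes on mouse-like chromosomes, drawing 1..max isoforms
#' per gene. Isoforms of a gene share chromosome and strand, and spread their
#' transcription start sites over <= 2 kb and their poly(A) sites over <= 5 kb
#' (sampled without replacement, so (TSS, PAS) pairs are distinct within a
#' gene). Exon structure, transcript support level, coding status and, for
#' coding isoforms, 5'UTR/CDS/3'UTR lengths are assigned per isoform.
#' Mitochondrial genes are named with the mouse `mt-` prefix; senescence
#' marker genes (`Sen01`, ...) always carry at least two isoforms.
#'
#' @param config a [simulation_config()].
#' @return data.frame of class `isoform_catalog` with one row per isoform and
#'   columns isoform_id, gene_id, chrom, strand, tss, pas, length, exon_count,
#'   coding, tsl, cds_length, utr5_length, utr3_length plus list-columns
#'   exon_starts/exon_ends (0-based half-open genomic intervals).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(child_seed(config$seed, "catalog"), {
    n <- config$n_genes
    gene_ids <- character(n)
    n_mt <- config$n_mt_genes
    n_sen <- config$n_marker_genes
    if (n_mt > 0) gene_ids[seq_len(n_mt)] <- sprintf("mt-%d", seq_len(n_mt))
    if (n_sen > 0) gene_ids[n_mt + seq_len(n_sen)] <- sprintf("Sen%02d", seq_len(n_sen))
    rest <- seq.int(n_mt + n_sen + 1L, n)
    gene_ids[rest] <- sprintf("G%04d", rest)

    rows <- vector("list", n)
    for (g in seq_len(n)) {
      is_marker <- g > n_mt && g <= n_mt + n_sen
      lo <- if (is_marker) max(2L, config$isoforms_min) else config$isoforms_min
      hi <- max(lo, config$isoforms_max)
      J <- if (lo == hi) lo else sample(lo:hi, 1L)
      chrom <- as.character(sample(1:19, 1L))
      strand <- sample(c("+", "-"), 1L)
      gstart <- sample.int(100000000L, 1L) + 10000L
      tss_off <- sample.int(2000L, J)  # distinct offsets, <= 2 kb spread
      pas_off <- sample.int(5000L, J)  # distinct offsets, <= 5 kb spread
      if (strand == "+") {
        tss <- gstart + tss_off
        pas <- gstart + 10000L + pas_off
      } else {
        tss <- gstart + 15000L - tss_off
        pas <- gstart + 5000L - pas_off
      }
      iso <- vector("list", J)
      for (k in seq_len(J)) {
        tx_start <- min(tss[k], pas[k])
        tx_end <- max(tss[k], pas[k]) + 1L
        span <- tx_end - tx_start
        e <- sample(1:5, 1L)
        parts <- 2L * e - 1L
        props <- rgamma(parts, shape = 1)
        widths <- 20L + floor(props / sum(props) * (span - 20L * parts))
        widths[parts] <- widths[parts] + (span - sum(widths))
        starts <- tx_start + c(0L, cumsum(widths))[seq_len(parts)]
        exon_idx <- seq(1L, parts, by = 2L)
        ex_start <- starts[exon_idx]
        ex_end <- ex_start + widths[exon_idx]
        len <- sum(widths[exon_idx])
        tsl <- if (runif(1) < config$tsl1_prob) 1L else sample(2:5, 1L)
        coding <- runif(1) < config$coding_prob
        utr5 <- utr3 <- cds <- NA_integer_
        if (coding) {
          utr5 <- max(1L, as.integer(floor(len * runif(1, 0.05, 0.2))))
          utr3 <- max(1L, as.integer(floor(len * runif(1, 0.1, 0.3))))
          cds <- len - utr5 - utr3
          if (cds < 3L) { coding <- FALSE; utr5 <- utr3 <- cds <- NA_integer_ }
        }
        iso[[k]] <- data.frame(
          isoform_id = sprintf("%s-%03d", gene_ids[g], 200L + k),
          gene_id = gene_ids[g], chrom = chrom, strand = strand,
          tss = tss[k], pas = pas[k], length = len, exon_count = e,
          coding = coding, tsl = tsl,
          cds_length = cds, utr5_length = utr5, utr3_length = utr3,
          stringsAsFactors = FALSE
        )
        iso[[k]]$exon_starts <- list(ex_start)
        iso[[k]]$exon_ends <- list(ex_end)
      }
      rows[[g]] <- do.call(rbind, iso)
    }
    cat <- do.call(rbind, rows)
    rownames(cat) <- cat$isoform_id
    class(cat) <- c("isoform_catalog", "data.frame")
    cat
  })
}

#' Generate synthetic cells
#'
#' Each design sample contributes `n_cells_per_sample` barcodes with cell
#' types drawn from the configured proportions. In non-young samples, the
#' configured fraction of immune cells is flagged senescent (ground truth).
#'
#' @param config a [simulation_config()].
#' @return data.frame of class `cell_table` with one row per barcode.
#' @export
generate_cells <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(config$design) == 0) stopf("design is empty")
  with_seed(child_seed(config$seed, "cells"), {
    des <- config$design
    per <- config$n_cells_per_sample
    n <- nrow(des) * per
    idx <- rep(seq_len(nrow(des)), each = per)
    cells <- data.frame(
      barcode = sprintf("%s:%06d", des$sample_id[idx], sequence(rep(per, nrow(des)))),
      sample_id = des$sample_id[idx],
      cell_type = sample(names(config$cell_type_proportions), n, replace = TRUE,
                         prob = config$cell_type_proportions),
      age_months = des$age_months[idx],
      age_category = des$age_category[idx],
      sex = des$sex[idx],
      region = des$region[idx],
      stringsAsFactors = FALSE
    )
    cells$senescent <- cells$cell_type == "immune" &
      cells$age_category != "young" &
      runif(n) < config$senescent_fraction
    cells$n_genes_detected <- NA_integer_
    cells$mito_fraction <- NA_real_
    class(cells) <- c("cell_table", "data.frame")
    cells
  })
}

# Baseline isoform usage simplex per gene; the planted target isoform is the
# minimum-usage one, so a shift of delta u always fits inside the simplex.
shift_usage <- function(pi, target, delta) {
  out <- pi * (1 - pi[target] - delta) / (1 - pi[target])
  out[target] <- pi[target] + delta
  out
}

#' Simulate a barcode x isoform UMI count matrix with planted effects
#'
#' Per cell and gene, the gene total is Poisson with a log-normal per-cell
#' depth factor and a rate proportional to the gene's baseline expression
#' times its temporal trajectory multiplier (and times `marker_fold` for
#' marker genes in senescent cells). The gene total is split across isoforms
#' by a Dirichlet-multinomial draw with concentration `precision_gamma`
#' around the cell's usage simplex: the baseline simplex, or the planted
#' shifted simplex for CIG genes (in their target cell type), AIG genes (in
#' old/geriatric cells), and marker genes (in senescent cells).
#'
#' @param catalog an `isoform_catalog` from [generate_catalog()].
#' @param cells a `cell_table` from [generate_cells()].
#' @param config the same [simulation_config()] used to build them.
#' @return list with `counts` (sparse dgCMatrix, barcodes x isoforms) and
#'   `truth` (list recording every planted effect: cig_genes, aig_genes,
#'   sen_usage_genes, trajectory_assignments, senescent_barcodes,
#'   baseline_usage, marker_genes).
#' @export
simulate_counts <- function(catalog, cells, config) {
  stopifnot(inherits(config, "simulation_config"))
  markers <- unique(catalog$gene_id[startsWith(catalog$gene_id, "Sen")])
  if (config$n_marker_genes > 0 && length(markers) == 0) {
    stopf("marker genes absent from catalog")
  }
  with_seed(child_seed(config$seed, "counts"), {
    genes <- unique(catalog$gene_id)
    n_genes <- length(genes)
    iso_by_gene <- split(seq_len(nrow(catalog)), catalog$gene_id)[genes]
    n_cells <- nrow(cells)

    ## baseline expression rates, with fixed total shares for mt and markers
    base <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
    names(base) <- genes
    is_mt <- startsWith(genes, "mt-")
    is_marker <- genes %in% markers
    other <- !is_mt & !is_marker
    base[other] <- base[other] / sum(base[other]) *
      (1 - config$mt_share - config$marker_share)
    if (any(is_mt)) base[is_mt] <- base[is_mt] / sum(base[is_mt]) * config$mt_share
    if (any(is_marker)) base[is_marker] <- base[is_marker] / sum(base[is_marker]) * config$marker_share

    ## trajectory assignment per gene; marker genes stay temporally flat so
    ## marker elevation is attributable to senescence alone
    n_shapes <- length(config$trajectory_cluster_shapes)
    traj <- sample.int(n_shapes, n_genes, replace = TRUE)
    names(traj) <- genes
    traj[is_marker] <- NA_integer_
    ages <- sort(unique(config$design$age_months))
    age_range <- range(config$design$age_months)
    samp_ages <- config$design$age_months
    names(samp_ages) <- config$design$sample_id
    mult_by_age <- vapply(seq_len(n_genes), function(g) {
      if (is.na(traj[g])) return(rep(1, length(ages)))
      trajectory_multiplier(config$trajectory_cluster_shapes[[traj[g]]], ages, age_range)
    }, numeric(length(ages)))
    if (length(ages) == 1L) mult_by_age <- matrix(mult_by_age, nrow = 1)
    dimnames(mult_by_age) <- list(as.character(ages), genes)

    ## planted usage effects
    J_per_gene <- lengths(iso_by_gene)
    eligible <- genes[J_per_gene >= 2 & !is_mt & !is_marker]
    n_cig <- round(config$cig_fraction * n_genes)
    n_aig <- round(config$aig_fraction * n_genes)
    if (n_cig + n_aig > length(eligible)) {
      stopf("not enough multi-isoform genes for the requested cig/aig fractions")
    }
    planted <- sample(eligible, n_cig + n_aig)
    cig_set <- head(planted, n_cig)
    aig_set <- planted[seq.int(n_cig + 1, length.out = n_aig)]
    ct_levels <- names(config$cell_type_proportions)

    pi_base <- lapply(iso_by_gene, function(ix) {
      J <- length(ix)
      p <- rgamma(J, shape = 3)
      p / sum(p)
    })
    cig_ct <- sample(ct_levels, n_cig, replace = TRUE)
    names(cig_ct) <- cig_set

    target_iso <- vapply(genes, function(g) which.min(pi_base[[g]]), integer(1))

    cell_age <- as.character(cells$age_months)
    sen <- cells$senescent
    aged <- cells$age_category %in% c("old", "geriatric")

    ## per-cell total rate (for share normalization)
    fold <- config$marker_fold
    tot_by_age <- colSums(base * t(mult_by_age))         # per age: sum_g base*mult
    tot_mark_by_age <- colSums((base * is_marker) * t(mult_by_age))
    names(tot_by_age) <- names(tot_mark_by_age) <- as.character(ages)
    T_c <- tot_by_age[cell_age] + (fold - 1) * tot_mark_by_age[cell_age] * sen

    depth_f <- rlnorm(n_cells, meanlog = -config$depth_sd_log^2 / 2,
                      sdlog = config$depth_sd_log)
    lam_scale <- config$depth_mean * depth_f / T_c

    gamma <- config$precision_gamma
    trip_i <- vector("list", n_genes)
    trip_j <- vector("list", n_genes)
    trip_x <- vector("list", n_genes)

    for (g in seq_len(n_genes)) {
      gid <- genes[g]
      ix <- iso_by_gene[[gid]]
      J <- length(ix)
      rate <- base[g] * mult_by_age[cell_age, g]
      if (is_marker[g]) rate <- rate * ifelse(sen, fold, 1)
      N <- rpois(n_cells, lam_scale * rate)
      if (J == 1L) {
        nz <- which(N > 0L)
        trip_i[[g]] <- nz; trip_j[[g]] <- rep(ix, length(nz)); trip_x[[g]] <- N[nz]
        next
      }
      pi0 <- pi_base[[gid]]
      sel <- rep(FALSE, n_cells)
      if (gid %in% cig_set) sel <- cells$cell_type == cig_ct[gid]
      if (gid %in% aig_set) sel <- aged
      if (is_marker[g]) sel <- sen
      pim <- matrix(pi0, n_cells, J, byrow = TRUE)
      if (any(sel)) {
        pim[sel, ] <- matrix(shift_usage(pi0, target_iso[g], config$usage_effect_size),
                             sum(sel), J, byrow = TRUE)
      }
      ## Dirichlet draw per cell, then multinomial split of N
      G <- matrix(rgamma(n_cells * J, shape = gamma * as.vector(pim)), n_cells, J)
      P <- G / rowSums(G)
      y <- matrix(0L, n_cells, J)
      rem <- N
      remp <- rep(1, n_cells)
      for (k in seq_len(J - 1L)) {
        pr <- pmin(1, pmax(0, P[, k] / pmax(remp, 1e-12)))
        y[, k] <- rbinom(n_cells, rem, pr)
        rem <- rem - y[, k]
        remp <- remp - P[, k]
      }
      y[, J] <- rem
      nz <- which(y > 0L, arr.ind = TRUE)
      trip_i[[g]] <- nz[, 1]
      trip_j[[g]] <- ix[nz[, 2]]
      trip_x[[g]] <- y[nz]
    }

    counts <- Matrix::sparseMatrix(
      i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
      dims = c(n_cells, nrow(catalog)),
      dimnames = list(cells$barcode, catalog$isoform_id)
    )
    counts <- as(counts, "CsparseMatrix")

    truth <- list(
      cig_genes = if (n_cig) data.frame(
        gene_id = cig_set, cell_type = unname(cig_ct[cig_set]),
        target_isoform = catalog$isoform_id[vapply(cig_set, function(g)
          iso_by_gene[[g]][target_iso[g]], integer(1))],
        stringsAsFactors = FALSE) else data.frame(),
      aig_genes = if (n_aig) data.frame(
        gene_id = aig_set, contrast = "young_vs_aged",
        target_isoform = catalog$isoform_id[vapply(aig_set, function(g)
          iso_by_gene[[g]][target_iso[g]], integer(1))],
        stringsAsFactors = FALSE) else data.frame(),
      sen_usage_genes = data.frame(
        gene_id = markers,
        target_isoform = catalog$isoform_id[vapply(markers, function(g)
          iso_by_gene[[g]][target_iso[g]], integer(1))],
        stringsAsFactors = FALSE),
      trajectory_assignments = setNames(
        unname(traj[catalog$gene_id]), catalog$isoform_id),
      senescent_barcodes = cells$barcode[cells$senescent],
      baseline_usage = pi_base,
      marker_genes = markers
    )
    list(counts = counts, truth = truth)
  })
}

#' Write a synthetic fixture to disk
#'
#' Emits the four study inputs plus ground truth: Matrix Market counts with
#' barcode/feature TSVs, an Ensembl-dialect GTF, a cell-metadata TSV, the
#' marker gene list, and `ground_truth.json`. The files round-trip through
#' [read_counts()], [parse_gtf()] and [read_cell_metadata()].
#'
#' @param catalog,cells,counts,truth generator outputs.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_fixture <- function(catalog, cells, counts, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create directory %s", out_dir)
  paths <- file.path(out_dir, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                                "annotation.gtf", "cell_metadata.tsv",
                                "markers.txt", "ground_truth.json"))
  names(paths) <- c("mtx", "barcodes", "features", "gtf", "cells", "markers", "truth")
  Matrix::writeMM(as(counts, "generalMatrix"), paths["mtx"])
  writeLines(rownames(counts), paths["barcodes"])
  write.table(data.frame(isoform_id = colnames(counts),
                         gene_id = catalog$gene_id[match(colnames(counts),
                                                         catalog$isoform_id)]),
              paths["features"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_gtf(catalog, paths["gtf"])
  write.table(as.data.frame(cells), paths["cells"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(truth$marker_genes, paths["markers"])
  jsonlite::write_json(list(
    cig_genes = truth$cig_genes,
    aig_genes = truth$aig_genes,
    sen_usage_genes = truth$sen_usage_genes,
    trajectory_assignments = as.list(truth$trajectory_assignments),
    senescent_barcodes = truth$senescent_barcodes,
    marker_genes = truth$marker_genes,
    catalog = as.data.frame(catalog)[, c("isoform_id", "gene_id", "tss", "pas",
                                         "length", "exon_count")]
  ), paths["truth"], auto_unbox = TRUE, digits = NA, null = "list")
  invisible(paths)
}

# Map a transcript-coordinate half-open interval [a, b) (measured from the 5'
# end in transcription direction) to genomic intervals through the exons.
tx_interval_to_genome <- function(ex_start, ex_end, strand, a, b) {
  w <- ex_end - ex_start
  if (strand == "-") {
    ord <- order(ex_start, decreasing = TRUE)
  } else {
    ord <- order(ex_start)
  }
  ws <- w[ord]
  offs <- c(0, cumsum(ws))
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(ord)) {
    lo <- max(a, offs[k]); hi <- min(b, offs[k + 1])
    if (lo >= hi) next
    if (strand == "+") {
      gs <- ex_start[ord[k]] + (lo - offs[k])
      ge <- gs + (hi - lo)
    } else {
      ge <- ex_end[ord[k]] - (lo - offs[k])
      gs <- ge - (hi - lo)
    }
    out_s <- c(out_s, gs); out_e <- c(out_e, ge)
  }
  list(start = out_s, end = out_e)
}

# Ensembl-dialect GTF writer (1-based inclusive coordinates).
write_gtf <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lines <- character(0)
  for (gid in unique(catalog$gene_id)) {
    sub <- catalog[catalog$gene_id == gid, , drop = FALSE]
    g_start <- min(vapply(sub$exon_starts, min, numeric(1)))
    g_end <- max(vapply(sub$exon_ends, max, numeric(1)))
    chrom <- sub$chrom[1]; strand <- sub$strand[1]
    lines <- c(lines, sprintf(
      '%s\tisousage\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
      chrom, g_start + 1, g_end, strand, gid))
    for (r in seq_len(nrow(sub))) {
      tid <- sub$isoform_id[r]
      es <- sub$exon_starts[[r]]; ee <- sub$exon_ends[[r]]
      biotype <- if (isTRUE(sub$coding[r])) "protein_coding" else "lncRNA"
      attr_tx <- sprintf(
        'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s"; transcript_support_level "%s";',
        gid, tid, biotype, sub$tsl[r])
      lines <- c(lines, sprintf('%s\tisousage\ttranscript\t%d\t%d\t.\t%s\t.\t%s',
                                chrom, min(es) + 1, max(ee), strand, attr_tx))
      ord <- if (strand == "+") order(es) else order(es, decreasing = TRUE)
      for (k in seq_along(ord)) {
        lines <- c(lines, sprintf(
          '%s\tisousage\texon\t%d\t%d\t.\t%s\t.\t%s exon_number "%d";',
          chrom, es[ord[k]] + 1, ee[ord[k]], strand, attr_tx, k))
      }
      if (isTRUE(sub$coding[r])) {
        a <- sub$utr5_length[r]
        b <- a + sub$cds_length[r]
        cdsg <- tx_interval_to_genome(es, ee, strand, a, b)
        for (k in seq_along(cdsg$start)) {
          lines <- c(lines, sprintf(
            '%s\tisousage\tCDS\t%d\t%d\t.\t%s\t0\t%s',
            chrom, cdsg$start[k] + 1, cdsg$end[k], strand, attr_tx))
        }
      }
    }
  }
  writeLines(lines, con)
}
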