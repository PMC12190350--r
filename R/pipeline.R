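#' Pipeline configuration
#'
#' Gathers every tunable of the analysis under named defaults: QC thresholds
#' (minimum 100 detected genes, 20% mitochondrial maximum, 98th-percentile
#' doublet rule), transcript filters (TSL 1, 0.5% prevalence), attribute bin
#' sizes (20 nt TSS, 75 nt PAS), significance thresholds (raw p < 0.05 for
#' cell-type and age scans, p < 0.01 for the trajectory screen, adjusted
#' p < 0.01 for marker discovery), senescence thresholds (5 / 4 / 7) and the
#' 90/5/5 classifier split. Input is either a [simulation_config()] or a set
#' of file paths (mtx/barcodes/features/gtf/cells/markers).
#'
#' @param input a `simulation_config`, or a named list of paths with elements
#'   mtx, barcodes, features, gtf, cells, markers.
#' @param out_dir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("data", "qc", "pseudobulk", "cig", "aig", "attributes",
#'   "trajectories", "senescence")`; disabling a stage disables its
#'   dependents with a message.
#' @param seed master seed.
#' @param p_cig,p_aig,p_traj,padj_sen significance thresholds.
#' @param tsl_required,min_cell_frac,mito_max,min_genes,top_pct filters.
#' @param tss_bin,pas_bin attribute bin sizes (nt).
#' @param target_sum,sen_threshold,ml_low,ml_high senescence scoring.
#' @param split classifier train/validation/test fractions.
#' @param K_candidates trajectory cluster candidates.
#' @param nrounds,early_stopping_rounds classifier boosting schedule.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = simulation_config(),
                            out_dir = tempfile("isousage_run_"),
                            stages = c("data", "qc", "pseudobulk", "cig",
                                       "aig", "attributes", "trajectories",
                                       "senescence"),
                            seed = 1L,
                            p_cig = 0.05, p_aig = 0.05, p_traj = 0.01,
                            padj_sen = 0.01,
                            tsl_required = 1, min_cell_frac = 0.005,
                            mito_max = 0.2, min_genes = 100, top_pct = 0.98,
                            tss_bin = 20, pas_bin = 75,
                            target_sum = 1e4, sen_threshold = 5,
                            ml_low = 4, ml_high = 7,
                            split = c(0.9, 0.05, 0.05),
                            K_candidates = c(8, 10, 12, 14),
                            nrounds = 10000, early_stopping_rounds = 50) {
  thresholds <- list(p_cig = p_cig, p_aig = p_aig, p_traj = p_traj,
                     padj_sen = padj_sen, tsl_required = tsl_required,
                     min_cell_frac = min_cell_frac, mito_max = mito_max,
                     min_genes = min_genes, top_pct = top_pct,
                     tss_bin = tss_bin, pas_bin = pas_bin,
                     target_sum = target_sum, sen_threshold = sen_threshold,
                     ml_low = ml_low, ml_high = ml_high)
  for (nm in c("p_cig", "p_aig", "p_traj", "padj_sen", "min_cell_frac",
               "mito_max", "top_pct")) {
    v <- thresholds[[nm]]
    if (v < 0 || v > 1) stopf("%s out of range [0, 1]", nm)
  }
  if (abs(sum(split) - 1) > 1e-9) stopf("split fractions must sum to 1")
  structure(list(
    schema_version = 1L,
    input = input, out_dir = out_dir, stages = stages, seed = as.integer(seed),
    thresholds = thresholds, split = split, K_candidates = K_candidates,
    nrounds = nrounds, early_stopping_rounds = early_stopping_rounds
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config a `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns the path invisibly. A config
#'   round-trips through write and read.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (inherits(x$input, "simulation_config")) {
    sim <- unclass(x$input)
    sim$design <- as.list(sim$design)
    sim$cell_type_proportions <- as.list(sim$cell_type_proportions)
    x$input <- list(simulation = sim)
  } else {
    x$input <- list(paths = x$input)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  input <- if (!is.null(x$input$simulation)) {
    sim <- x$input$simulation
    do.call(simulation_config, list(
      n_genes = sim$n_genes,
      isoforms_per_gene = c(sim$isoforms_min, sim$isoforms_max),
      n_cells_per_sample = sim$n_cells_per_sample,
      design = as.data.frame(sim$design, stringsAsFactors = FALSE),
      cell_type_proportions = unlist(sim$cell_type_proportions),
      cig_fraction = sim$cig_fraction, aig_fraction = sim$aig_fraction,
      usage_effect_size = sim$usage_effect_size,
      trajectory_cluster_shapes = lapply(sim$trajectory_cluster_shapes, unlist),
      senescent_fraction = sim$senescent_fraction,
      marker_fold = sim$marker_fold, n_marker_genes = sim$n_marker_genes,
      marker_share = sim$marker_share,
      n_mt_genes = sim$n_mt_genes, mt_share = sim$mt_share,
      precision_gamma = sim$precision_gamma, depth_mean = sim$depth_mean,
      depth_sd_log = sim$depth_sd_log, tsl1_prob = sim$tsl1_prob,
      coding_prob = sim$coding_prob, seed = sim$seed))
  } else {
    x$input$paths
  }
  th <- x$thresholds
  pipeline_config(input = input, out_dir = x$out_dir,
                  stages = unlist(x$stages), seed = x$seed,
                  p_cig = th$p_cig, p_aig = th$p_aig, p_traj = th$p_traj,
                  padj_sen = th$padj_sen, tsl_required = th$tsl_required,
                  min_cell_frac = th$min_cell_frac, mito_max = th$mito_max,
                  min_genes = th$min_genes, top_pct = th$top_pct,
                  tss_bin = th$tss_bin, pas_bin = th$pas_bin,
                  target_sum = th$target_sum, sen_threshold = th$sen_threshold,
                  ml_low = th$ml_low, ml_high = th$ml_high,
                  split = unlist(x$split), K_candidates = unlist(x$K_candidates),
                  nrounds = x$nrounds,
                  early_stopping_rounds = x$early_stopping_rounds)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full isoform-usage analysis pipeline
#'
#' Executes the enabled stages in dependency order — data
#' (simulation or ingestion), barcode/transcript QC, pseudobulk +
#' normalization + usage, cell-type usage scans (one vs rest per cell type),
#' age usage scans (young vs each later age), usage-weighted attribute
#' deltas and correlations, trajectory screening/clustering and length-shift
#' analysis, and senescence scoring, marker discovery, PCA and
#' classification — writing TSV outputs and a JSON manifest (file hashes,
#' seed, package version) into the output directory. Reruns with an
#' identical config reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("data", "qc", "pseudobulk", "cig", "aig", "attributes",
                  "trajectories", "senescence")
  deps <- list(data = character(), qc = "data", pseudobulk = "qc",
               cig = "pseudobulk", aig = "pseudobulk", attributes = "cig",
               trajectories = "pseudobulk", senescence = "pseudobulk")
  enabled <- intersect(all_stages, config$stages)
  repeat {
    drop <- enabled[!vapply(enabled, function(s)
      all(deps[[s]] %in% enabled), logical(1))]
    if (!length(drop)) break
    message("disabling stage(s) with unmet dependencies: ",
            paste(drop, collapse = ", "))
    enabled <- setdiff(enabled, drop)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  manifest <- list(schema_version = config$schema_version, seed = config$seed,
                   package_version = as.character(utils::packageVersion("isousage")),
                   stages = enabled, outputs = list())
  out <- list()
  files <- character()
  current <- "init"
  record <- function(path) files <<- c(files, path)
  finish_manifest <- function() {
    manifest$outputs <<- lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result <- tryCatch({
    if ("data" %in% enabled) {
      current <- "data"
      if (inherits(config$input, "simulation_config")) {
        sim <- config$input
        out$catalog <- generate_catalog(sim)
        out$cells <- generate_cells(sim)
        simc <- simulate_counts(out$catalog, out$cells, sim)
        out$counts <- simc$counts
        out$truth <- simc$truth
        out$markers <- simc$truth$marker_genes
      } else {
        p <- config$input
        out$catalog <- parse_gtf(p$gtf)
        out$counts <- read_counts(p$mtx, p$barcodes, p$features)
        out$cells <- read_cell_metadata(p$cells)
        out$markers <- readLines(p$markers)
      }
    }
    if ("qc" %in% enabled) {
      current <- "qc"
      fb <- filter_barcodes(out$counts, out$cells, out$catalog,
                            mito_max = th$mito_max, min_genes = th$min_genes,
                            top_pct = th$top_pct)
      ft <- filter_transcripts(fb$counts, out$catalog, fb$cells,
                               min_cell_frac = th$min_cell_frac,
                               tsl_required = th$tsl_required)
      out$counts_qc <- ft
      out$cells_qc <- fb$cells
      record(write_tsv(as.data.frame(fb$cells), file.path(config$out_dir, "cells_qc.tsv")))
    }
    if ("pseudobulk" %in% enabled) {
      current <- "pseudobulk"
      out$pb <- pseudobulk(out$counts_qc, out$cells_qc)
      out$sf <- size_factors(out$pb)
      out$usage <- isoform_usage(out$pb, out$catalog)
      record(write_tsv(data.frame(unit = names(out$sf), size_factor = out$sf),
                       file.path(config$out_dir, "size_factors.tsv")))
      um <- data.frame(unit = rownames(out$usage),
                       as.data.frame(out$usage, check.names = FALSE))
      record(write_tsv(um, file.path(config$out_dir, "usage.tsv")))
      Matrix::writeMM(as(Matrix::Matrix(out$pb$counts, sparse = TRUE),
                         "generalMatrix"),
                      file.path(config$out_dir, "pseudobulk.mtx"))
      record(file.path(config$out_dir, "pseudobulk.mtx"))
    }
    if ("cig" %in% enabled) {
      current <- "cig"
      out$cig <- list()
      for (ct in unique(out$pb$units$cell_type)) {
        grp <- ifelse(out$pb$units$cell_type == ct, ct, "rest")
        scan <- run_usage_scan(out$pb, out$catalog, grp, focus = ct,
                               alpha = th$p_cig)
        out$cig[[ct]] <- scan
        record(write_tsv(scan$gene_table,
                         file.path(config$out_dir, sprintf("cig_%s_genes.tsv", ct))))
        record(write_tsv(scan$isoform_table,
                         file.path(config$out_dir, sprintf("cig_%s_isoforms.tsv", ct))))
      }
    }
    if ("aig" %in% enabled) {
      current <- "aig"
      out$aig <- list()
      acs <- intersect(AGE_CATEGORIES, unique(out$pb$units$age_category))
      for (ac in setdiff(acs, "young")) {
        grp <- ifelse(out$pb$units$age_category == "young", "young",
                      ifelse(out$pb$units$age_category == ac, ac, NA))
        scan <- run_usage_scan(out$pb, out$catalog, grp, focus = ac,
                               alpha = th$p_aig)
        out$aig[[paste0("young_vs_", ac)]] <- scan
        record(write_tsv(scan$gene_table,
                         file.path(config$out_dir,
                                   sprintf("aig_young_vs_%s_genes.tsv", ac))))
      }
    }
    if ("attributes" %in% enabled) {
      current <- "attributes"
      attrs <- isoform_attributes(out$catalog, th$tss_bin, th$pas_bin)
      out$attrs <- attrs
      delta_all <- list()
      pair_changes <- list()
      for (ct in names(out$cig)) {
        scan <- out$cig[[ct]]
        sig <- scan$significant_genes
        if (!length(sig)) next
        grp <- ifelse(out$pb$units$cell_type == ct, ct, "rest")
        d <- attribute_deltas(out$usage, grp, ct, attrs, genes = sig)
        if (nrow(d)) { d$cell_type <- ct; delta_all[[ct]] <- d }
        for (gid in sig) {
          fr <- scan$isoform_table[scan$isoform_table$gene_id == gid, ]
          ch <- classify_pair_change(fr, attrs)
          if (!is.null(ch)) {
            pair_changes[[paste(ct, gid)]] <- data.frame(
              cell_type = ct, gene_id = gid,
              attribute = if (length(ch)) ch else NA_character_,
              stringsAsFactors = FALSE)
          }
        }
      }
      out$deltas <- do.call(rbind, delta_all)
      out$pair_changes <- do.call(rbind, pair_changes)
      if (!is.null(out$deltas)) {
        record(write_tsv(out$deltas, file.path(config$out_dir, "attribute_deltas.tsv")))
        corr <- delta_correlations(out$deltas)
        out$delta_corr <- corr
        cm <- data.frame(attribute = rownames(corr$rho),
                         as.data.frame(corr$rho, check.names = FALSE))
        record(write_tsv(cm, file.path(config$out_dir, "delta_correlations.tsv")))
      }
      if (!is.null(out$pair_changes)) {
        record(write_tsv(out$pair_changes, file.path(config$out_dir, "pair_changes.tsv")))
      }
    }
    if ("trajectories" %in% enabled &&
        length(unique(out$pb$units$age_months)) < 4) {
      message("trajectory stage skipped: fewer than 4 age timepoints")
      enabled <- setdiff(enabled, "trajectories")
    }
    if ("trajectories" %in% enabled) {
      current <- "trajectories"
      tr <- trajectory_traces(out$pb, out$sf)
      out$traces <- tr
      scr <- screen_trajectories(tr, p_threshold = th$p_traj)
      out$traj_screen <- scr
      record(write_tsv(cbind(trace = rownames(scr), scr),
                       file.path(config$out_dir, "trajectory_screen.tsv")))
      passing <- which(scr$pass)
      if (length(passing) > max(config$K_candidates)) {
        sel <- tr$values[passing, , drop = FALSE]
        cl <- cluster_trajectories(sel, tr$ages,
                                   K_candidates = config$K_candidates,
                                   seed = child_seed(config$seed, "clusters"))
        out$traj_clusters <- cl
        record(write_tsv(data.frame(trace = names(cl$assignments),
                                    cluster = cl$assignments),
                         file.path(config$out_dir, "trajectory_clusters.tsv")))
        record(write_tsv(data.frame(cluster = seq_len(cl$K), cl$mean_curves,
                                    variance = cl$cluster_variances,
                                    weight = cl$weights),
                         file.path(config$out_dir, "trajectory_mean_curves.tsv")))
      }
      out$expr_change <- expression_change_summary(tr)
      record(write_tsv(out$expr_change,
                       file.path(config$out_dir, "expression_change_summary.tsv")))
      oldest <- AGE_CATEGORIES[max(match(out$pb$units$age_category, AGE_CATEGORIES))]
      ls <- length_shift_analysis(out$pb, out$sf, out$catalog,
                                  age_pair = c("young", oldest))
      out$length_shift <- ls
      record(write_tsv(ls$tests, file.path(config$out_dir, "length_shift_tests.tsv")))
    }
    if ("senescence" %in% enabled) {
      current <- "senescence"
      sc <- senescence_score(out$counts_qc, out$cells_qc, out$markers,
                             out$catalog, target_sum = th$target_sum,
                             sen_threshold = th$sen_threshold,
                             ml_low = th$ml_low, ml_high = th$ml_high)
      out$scores <- sc
      record(write_tsv(as.data.frame(sc), file.path(config$out_dir, "senescence_scores.tsv")))
      out$sen_prop <- senescence_proportions(sc, out$cells_qc)
      record(write_tsv(out$sen_prop,
                       file.path(config$out_dir, "senescence_proportions.tsv")))
      disc <- tryCatch(
        discover_markers(out$counts_qc, out$cells_qc, sc, out$catalog,
                         padj_threshold = th$padj_sen),
        error = function(e) { message("marker discovery skipped: ",
                                      conditionMessage(e)); NULL })
      out$discovered <- disc
      if (!is.null(disc) && length(disc$genes) >= 1) {
        record(write_tsv(data.frame(gene_id = disc$genes),
                         file.path(config$out_dir, "senescence_marker_genes.tsv")))
        feats <- cell_usage_features(out$counts_qc, out$catalog, disc$genes)
        imm <- out$cells_qc$cell_type == "immune"
        pca <- usage_pca(feats[imm, , drop = FALSE])
        out$pca <- pca
        labels <- sc$ml_label
        lab_ok <- imm & !is.na(labels)
        if (length(unique(labels[lab_ok])) == 2 && sum(lab_ok) >= 40) {
          strata <- interaction(out$cells_qc$age_category,
                                out$cells_qc$sex, out$cells_qc$region)[lab_ok]
          clf <- tryCatch(
            train_classifier(feats[lab_ok, , drop = FALSE], labels[lab_ok],
                             strata = strata, split = config$split,
                             nrounds = config$nrounds,
                             early_stopping_rounds = config$early_stopping_rounds,
                             seed = child_seed(config$seed, "classifier")),
            error = function(e) { message("classifier skipped: ",
                                          conditionMessage(e)); NULL })
          out$classifier <- clf
          if (!is.null(clf)) {
            record(write_tsv(clf$roc, file.path(config$out_dir, "roc_points.tsv")))
            out$predicted <- predict_scores(clf, feats)
            record(write_tsv(data.frame(barcode = rownames(feats)[imm],
                                        prob = out$predicted[imm]),
                             file.path(config$out_dir, "predicted_senescence.tsv")))
            xgboost::xgb.save(clf$model,
                              file.path(config$out_dir, "classifier.model.ubj"))
            jsonlite::write_json(list(features = clf$feature_names),
                                 file.path(config$out_dir, "classifier_features.json"),
                                 auto_unbox = TRUE)
            record(file.path(config$out_dir, "classifier_features.json"))
          }
        }
      }
    }
    finish_manifest()
    out$manifest <- manifest
    out
  }, error = function(e) {
    manifest$failed_stage <<- current
    finish_manifest()
    stopf("pipeline failed in stage '%s': %s", current, conditionMessage(e))
  })
  invisible(result)
}
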