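# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small default-structure simulation used across modules.
tiny_sim <- function() {
  memo("tiny_sim", function() {
    cfg <- simulation_config(n_genes = 120, n_cells_per_sample = 60, seed = 42)
    catalog <- generate_catalog(cfg)
    cells <- generate_cells(cfg)
    sim <- simulate_counts(catalog, cells, cfg)
    list(config = cfg, catalog = catalog, cells = cells,
         counts = sim$counts, truth = sim$truth)
  })
}

# Senescence-enriched simulation for discovery/classification checks.
sen_sim <- function() {
  memo("sen_sim", function() {
    cfg <- simulation_config(
      n_genes = 300, n_cells_per_sample = 250,
      cell_type_proportions = c(neuron = 0.2, oligo = 0.15, astrocyte = 0.1,
                                vascular = 0.05, immune = 0.5),
      senescent_fraction = 0.2, seed = 4)
    catalog <- generate_catalog(cfg)
    cells <- generate_cells(cfg)
    sim <- simulate_counts(catalog, cells, cfg)
    list(config = cfg, catalog = catalog, cells = cells,
         counts = sim$counts, truth = sim$truth)
  })
}

# Minimal catalog data.frame for constructed count matrices: one row per
# isoform, single-exon genes, all TSL 1 unless stated.
toy_catalog <- function(gene_ids, isoform_ids = NULL, tsl = 1L) {
  isoform_ids <- isoform_ids %||% paste0(gene_ids, "-201")
  data.frame(
    isoform_id = isoform_ids, gene_id = gene_ids, chrom = "1", strand = "+",
    tss = seq_along(isoform_ids) * 1000L,
    pas = seq_along(isoform_ids) * 1000L + 500L,
    length = 500L, exon_count = 1L, coding = TRUE,
    tsl = rep_len(tsl, length(isoform_ids)),
    cds_length = NA_integer_, utr5_length = NA_integer_,
    utr3_length = NA_integer_, stringsAsFactors = FALSE
  )
}

toy_cells <- function(n, cell_type = "immune", sample_id = "S01",
                      age_months = 4, sex = "F", region = "cortex") {
  data.frame(
    barcode = sprintf("BC%05d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    cell_type = rep_len(cell_type, n),
    age_months = rep_len(age_months, n),
    age_category = as.character(isousage:::age_category_of(rep_len(age_months, n))),
    sex = rep_len(sex, n), region = rep_len(region, n),
    stringsAsFactors = FALSE
  )
}

# Hand-built pseudobulk container for direct unit tests.
toy_pseudobulk <- function(counts, units) {
  structure(list(counts = counts, units = units),
            class = "pseudobulk_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
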