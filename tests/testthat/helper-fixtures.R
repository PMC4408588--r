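# Shared simulated experiments, built once per test run and cached.
# All fixtures use fixed seeds so every run sees identical data.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small catalog for structural checks.
fx_catalog <- function() {
  fx_cache("catalog", function() generate_gene_catalog(400, seed = 101))
}

# Null experiment: no transcriptional or translational effects; the
# only structure in the arrays is the injected technical bias.
fx_null_experiment <- function() {
  fx_cache("null_exp", function() {
    catalog <- generate_gene_catalog(1200, seed = 202)
    truth <- generate_ground_truth(
      catalog, effects = effect_params(de_fraction = 0, ts_fraction = 0),
      seed = 202)
    abund <- suppressWarnings(
      simulate_fraction_abundances(truth, catalog, seed = 202))
    sheet <- make_sample_sheet()
    arrays <- simulate_arrays(abund, sheet, seed = 202)
    list(catalog = catalog, truth = truth, abund = abund,
         sheet = sheet, arrays = arrays)
  })
}

# Effect experiment: transcriptional spikes at exactly |log2FC| = 1.5
# and translational-state spikes at exactly {0.5, 2.0}.
fx_effect_experiment <- function() {
  fx_cache("effect_exp", function() {
    catalog <- generate_gene_catalog(1500, seed = 303)
    truth <- generate_ground_truth(
      catalog,
      effects = effect_params(de_fraction = 0.10,
                              de_log2fc_range = c(1.5, 1.5),
                              ts_fraction = 0.05,
                              ts_fold_range = c(2, 2)),
      seed = 303)
    abund <- suppressWarnings(
      simulate_fraction_abundances(truth, catalog, seed = 303))
    sheet <- make_sample_sheet()
    arrays <- simulate_arrays(abund, sheet, seed = 303)
    expr <- normalize_arrays(arrays)
    list(catalog = catalog, truth = truth, abund = abund,
         sheet = sheet, arrays = arrays, expr = expr)
  })
}

# Translational-state recovery experiment: two conditions at a low
# polysome share (P:M = 0.7) so that a 2-fold enrichment is physically
# representable (share x 2 stays below the ceiling); spikes at exactly
# {0.5, 2.0}.
fx_ts_recovery_experiment <- function() {
  fx_cache("ts_exp", function() {
    catalog <- generate_gene_catalog(1200, seed = 505)
    design <- data.frame(condition = c("D", "X"),
                         control = c(TRUE, FALSE))
    truth <- generate_ground_truth(
      catalog, design,
      effects = effect_params(de_fraction = 0,
                              ts_fraction = 0.05,
                              ts_fold_range = c(2, 2),
                              pm_ratio = c(D = 0.7, X = 0.7)),
      seed = 505)
    abund <- suppressWarnings(
      simulate_fraction_abundances(truth, catalog, seed = 505))
    sheet <- make_sample_sheet(design)
    arrays <- simulate_arrays(abund, sheet, seed = 505)
    expr <- normalize_arrays(arrays)
    list(catalog = catalog, truth = truth, expr = expr)
  })
}

# Orthogonality experiment: strong transcriptional spikes, all true
# translational states at 1.
fx_transcription_only_experiment <- function() {
  fx_cache("txn_exp", function() {
    catalog <- generate_gene_catalog(1200, seed = 404)
    truth <- generate_ground_truth(
      catalog,
      effects = effect_params(de_fraction = 0.3,
                              de_log2fc_range = c(1, 3),
                              ts_fraction = 0),
      seed = 404)
    abund <- suppressWarnings(
      simulate_fraction_abundances(truth, catalog, seed = 404))
    sheet <- make_sample_sheet()
    arrays <- simulate_arrays(abund, sheet, seed = 404)
    expr <- normalize_arrays(arrays)
    list(catalog = catalog, truth = truth, expr = expr)
  })
}

# Bare expression table around a numeric matrix (genes x samples).
fx_expr_table <- function(E, condition, replicate,
                          fraction = "total") {
  samples <- data.frame(
    sample_id = paste(condition, replicate, fraction, sep = "."),
    condition = condition, replicate = replicate, fraction = fraction,
    stringsAsFactors = FALSE
  )
  if (is.null(rownames(E))) {
    rownames(E) <- sprintf("g%04d", seq_len(nrow(E)))
  }
  colnames(E) <- samples$sample_id
  structure(list(E = E, samples = samples), class = "expr_table")
}
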