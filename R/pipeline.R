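# End-to-end orchestration: simulate -> profiles -> normalize -> de ->
# ts -> features -> growth -> report, communicating only through
# documented TSV/FASTA files so every stage can be rerun or replaced
# independently. A manifest records inputs (md5), parameters and the
# seed for each stage.

#' Default pipeline configuration
#'
#' @param seed Master seed; all stage streams derive from it.
#' @param outdir Output directory.
#' @param n_genes Catalog size for the simulate stage.
#' @param n_replicates Biological replicates per condition.
#' @param span Loess span for colour normalization.
#' @param fc,alpha Regulation call cutoffs (fold change, adjusted p).
#' @param control Control condition id.
#' @return Nested list of class `run_config` with one block per stage.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("run"),
                               n_genes = 600, n_replicates = 3,
                               span = 0.3, fc = 1.5, alpha = 0.05,
                               control = "D") {
  structure(
    list(
      seed = as.integer(seed),
      outdir = outdir,
      control = control,
      simulate = list(n_genes = n_genes, n_replicates = n_replicates),
      normalize = list(span = span),
      de = list(fc = fc, alpha = alpha),
      ts = list(fc = fc, alpha = alpha),
      growth = list()
    ),
    class = "run_config"
  )
}

#' Read / write a pipeline configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

pipeline_stages <- function() {
  c("simulate", "profiles", "normalize", "de", "ts", "features",
    "growth", "report")
}

stage_requirements <- function() {
  list(
    simulate = character(0),
    profiles = "trace_manifest.tsv",
    normalize = c("intensities.tsv", "sample_sheet.tsv"),
    de = "expr.tsv",
    ts = "expr.tsv",
    features = c("catalog.tsv", "cds.fa", "intensities.tsv",
                 "sample_sheet.tsv", "ts_table.tsv"),
    growth = character(0),
    report = character(0)
  )
}

manifest_add <- function(outdir, stage, files, seed, params) {
  entry <- list(
    stage = stage,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed,
    params = params,
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(outdir, "manifest.json")
  existing <- if (file.exists(path)) {
    jsonlite::read_json(path)
  } else list()
  existing[[stage]] <- entry
  jsonlite::write_json(existing, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order over one output directory.
#' Stages talk only through files, so a stage can be rerun alone as
#' long as its inputs exist; a missing dependency is an error naming
#' the missing stage output. Identical config and seed give identical
#' outputs.
#'
#' @param config A [default_run_config()] list.
#' @param stages Ordered subset of
#'   simulate, profiles, normalize, de, ts, features, growth, report.
#' @return Invisibly, a list with the outdir and per-stage output file
#'   paths.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = pipeline_stages()) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- list()
  p <- function(f) file.path(outdir, f)

  for (stage in pipeline_stages()[pipeline_stages() %in% stages]) {
    need <- stage_requirements()[[stage]]
    missing <- need[!file.exists(file.path(outdir, need))]
    if (length(missing)) {
      stop(sprintf(
        "stage '%s' requires missing output(s) %s; run the producing stage first",
        stage, paste(missing, collapse = ", ")), call. = FALSE)
    }
    outputs[[stage]] <- switch(
      stage,
      simulate = stage_simulate(config, p),
      profiles = stage_profiles(config, p),
      normalize = stage_normalize(config, p),
      de = stage_de(config, p),
      ts = stage_ts(config, p),
      features = stage_features(config, p),
      growth = stage_growth(config, p),
      report = stage_report(config, p)
    )
    manifest_add(outdir, stage, outputs[[stage]], seed,
                 config[[stage]])
  }
  invisible(list(outdir = outdir, outputs = outputs))
}

stage_simulate <- function(config, p) {
  n_genes <- config$simulate$n_genes
  n_rep <- config$simulate$n_replicates
  catalog <- generate_gene_catalog(n_genes, seed = config$seed)
  truth <- generate_ground_truth(catalog, seed = config$seed)
  abund <- simulate_fraction_abundances(truth, catalog,
                                        n_replicates = n_rep,
                                        seed = config$seed)
  sheet <- make_sample_sheet(truth$design, n_replicates = n_rep)
  arrays <- simulate_arrays(abund, sheet, seed = config$seed)

  write_catalog(catalog, p("catalog.tsv"))
  write_cds_fasta(catalog, p("cds.fa"))
  write_ground_truth(truth, p("ground_truth.tsv"))
  write_sample_sheet(sheet, p("sample_sheet.tsv"))
  write_intensities(arrays, p("intensities.tsv"))

  tman <- data.frame(condition = names(truth$pm_ratio),
                     file = paste0("trace_", names(truth$pm_ratio),
                                   ".tsv"),
                     pm_true = unname(truth$pm_ratio),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tman))) {
    sim <- simulate_profile_trace(tman$pm_true[i],
                                  seed = config$seed + i)
    write_trace(sim$trace, p(tman$file[i]))
  }
  write_tsv(tman, p("trace_manifest.tsv"))
  c(p("catalog.tsv"), p("cds.fa"), p("ground_truth.tsv"),
    p("sample_sheet.tsv"), p("intensities.tsv"),
    p("trace_manifest.tsv"), p(tman$file))
}

stage_profiles <- function(config, p) {
  tman <- read_tsv(p("trace_manifest.tsv"))
  res <- do.call(rbind, lapply(seq_len(nrow(tman)), function(i) {
    tr <- read_trace(p(tman$file[i]))
    pm <- analyze_trace(tr)
    data.frame(condition = tman$condition[i],
               pm_ratio = pm$pm_ratio,
               monosome_area = pm$areas[["monosome"]],
               polysome_area = pm$areas[["polysome"]],
               stringsAsFactors = FALSE)
  }))
  write_tsv(res, p("profiles.tsv"))
  p("profiles.tsv")
}

stage_normalize <- function(config, p) {
  sheet <- read_sample_sheet(p("sample_sheet.tsv"))
  raw <- read_intensities(p("intensities.tsv"), sheet)
  span <- config$normalize$span
  ma <- compute_ma(raw)
  trend_pre <- ma_trend_magnitude(ma, span = span)
  ma <- loess_normalize(ma, span = span)
  trend_post <- ma_trend_magnitude(ma, span = span)
  expr <- quantile_normalize(combine_dye_swaps(ma))
  write_expr_table(expr, p("expr.tsv"))
  write_tsv(data.frame(array_id = names(trend_pre),
                       max_abs_trend_raw = unname(trend_pre),
                       max_abs_trend_normalized = unname(trend_post)),
            p("qc_loess_trends.tsv"))
  qc <- pca_qc(expr)
  write_tsv(data.frame(component = seq_along(qc$var_explained),
                       var_explained = qc$var_explained),
            p("pca.tsv"))
  c(p("expr.tsv"), p("qc_loess_trends.tsv"), p("pca.tsv"))
}

stage_de <- function(config, p) {
  expr <- read_expr_table(p("expr.tsv"))
  tab <- fit_condition_contrasts(expr, control = config$control)
  tab <- call_regulated(tab, fc = config$de$fc,
                        alpha = config$de$alpha)
  write_tsv(tab, p("contrasts.tsv"))
  for (dir in c("up", "down")) {
    sets <- regulated_sets(tab, dir)
    if (length(sets) == 3) {
      vp <- venn_partition(sets)
      write_tsv(data.frame(region = names(vp), count = as.integer(vp)),
                p(paste0("venn_", dir, ".tsv")))
    }
  }
  p("contrasts.tsv")
}

stage_ts <- function(config, p) {
  expr <- read_expr_table(p("expr.tsv"))
  ts <- compute_translational_state(expr)
  rel <- relative_ts(ts, control = config$control,
                     fc = config$ts$fc, alpha = config$ts$alpha)
  write_tsv(rel, p("ts_contrasts.tsv"))
  df <- data.frame(gene_id = rownames(ts$mean_log_ts),
                   ts$mean_log_ts, check.names = FALSE)
  write_tsv(df, p("ts_table.tsv"))
  c(p("ts_contrasts.tsv"), p("ts_table.tsv"))
}

stage_features <- function(config, p) {
  catalog <- read_catalog(p("catalog.tsv"))
  catalog$cds <- unname(read_cds_fasta(p("cds.fa"))[catalog$gene_id])
  sheet <- read_sample_sheet(p("sample_sheet.tsv"))
  raw <- read_intensities(p("intensities.tsv"), sheet)
  expr <- expression_intensity(raw)
  ts_means <- read_tsv(p("ts_table.tsv"), check.names = FALSE)
  ts <- structure(list(
    mean_log_ts = as.matrix(ts_means[, -1, drop = FALSE]) |>
      `rownames<-`(ts_means$gene_id)
  ), class = "ts_table")
  gs <- summarize_groups(catalog, expr, ts)
  at <- association_tests(catalog, expr, ts)
  write_tsv(gs, p("group_stats.tsv"))
  write_tsv(at, p("association_tests.tsv"))
  c(p("group_stats.tsv"), p("association_tests.tsv"))
}

stage_growth <- function(config, p) {
  params <- do.call(growth_params, config$growth)
  feed <- release_rate(params$t, params = params)
  mu <- growth_rate(feed, params)
  sens <- sensitivity_range(params, feed)
  df <- data.frame(
    quantity = c("cumulative_release_mg_per_disc", "feed_rate_mg_h",
                 "mu_h", "mu_min_h", "mu_max_h"),
    value = c(cumulative_release(params$t, params), feed, mu,
              sens$mu_min, sens$mu_max),
    stringsAsFactors = FALSE
  )
  write_tsv(df, p("growth.tsv"))
  p("growth.tsv")
}

stage_report <- function(config, p) {
  lines <- c("# Pipeline report", "")
  if (file.exists(p("profiles.tsv"))) {
    pr <- read_tsv(p("profiles.tsv"))
    lines <- c(lines, "## P:M ratios per condition", "",
               sprintf("- %s: %.2f", pr$condition, pr$pm_ratio), "")
  }
  if (file.exists(p("contrasts.tsv"))) {
    tab <- read_tsv(p("contrasts.tsv"))
    cnt <- aggregate(gene_id ~ contrast + call, tab, length)
    reg <- cnt[cnt$call != "ns", ]
    lines <- c(lines, "## Regulated genes per contrast", "",
               if (nrow(reg)) sprintf("- %s %s: %d", reg$contrast,
                                      reg$call, reg$gene_id)
               else "- none", "")
  }
  if (file.exists(p("ts_contrasts.tsv"))) {
    ts <- read_tsv(p("ts_contrasts.tsv"))
    cnt <- aggregate(gene_id ~ condition + call, ts, length)
    reg <- cnt[cnt$call != "ns", ]
    lines <- c(lines, "## Translational-state changes per condition",
               "",
               if (nrow(reg)) sprintf("- %s %s: %d", reg$condition,
                                      reg$call, reg$gene_id)
               else "- none", "")
  }
  if (file.exists(p("group_stats.tsv"))) {
    gs <- read_tsv(p("group_stats.tsv"))
    lines <- c(lines, "## Length-group summary", "",
               sprintf(
                 "- %s: n=%d, mean length %.0f bp, mean SCUO %.3f, 5'UTR %.0f%%",
                 gs$group, gs$n_genes, gs$mean_orf_length,
                 gs$mean_scuo, gs$pct_utr5), "")
  }
  if (file.exists(p("growth.tsv"))) {
    gr <- read_tsv(p("growth.tsv"))
    lines <- c(lines, "## Feed-bead growth model", "",
               sprintf("- %s: %.4g", gr$quantity, gr$value), "")
  }
  writeLines(lines, p("report.md"))
  p("report.md")
}
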