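#' Catalog generation parameters
#'
#' Controls the synthetic gene catalog. ORF lengths follow a log-normal
#' distribution (right-skewed, mean > median as observed for the
#' *P. pastoris* annotation: mean 1444 bp, median 1203 bp) truncated to
#' the observed range 141--14853 bp. 5'UTR presence, codon-usage bias
#' (SCUO) and baseline transcript abundance all depend on the gene's
#' length group, reproducing the annotated trends: long genes usually
#' carry a 5'UTR (50%) and have weak codon bias; short genes rarely do
#' (2%) and are strongly biased and highly expressed.
#'
#' @param meanlog,sdlog Log-normal parameters of ORF length in bp;
#'   defaults solve median = 1203 and mean = 1444 exactly for the
#'   untruncated law (truncation mass is < 0.1%).
#' @param length_range Truncation bounds in bp.
#' @param utr_prob Probability of a 5'UTR per length group
#'   (long/medium/short).
#' @param utr_meanlog,utr_sdlog Log-normal parameters of 5'UTR length.
#' @param scuo_target Target mean SCUO per length group (long/medium/short).
#' @param scuo_sd Gene-to-gene spread around the group target.
#' @param abundance_meanlog2 Baseline log2 abundance at the median length.
#' @param abundance_slope Decrease in log2 abundance per log2 length unit
#'   (negative length--expression correlation).
#' @param abundance_sdlog2 Gene-to-gene log2 abundance spread.
#' @param ts_length_slope Decrease in log2 polysome affinity per log2
#'   length unit: short transcripts sit relatively deeper in the
#'   polysome fraction (group-mean log2 affinity about +0.18 for short
#'   and -0.2 for long genes).
#' @param ts_affinity_sd Gene-to-gene log2 affinity spread.
#' @return A list of class `catalog_params`.
#' @export
catalog_params <- function(meanlog = log(1203),
                           sdlog = sqrt(2 * log(1444 / 1203)),
                           length_range = c(141L, 14853L),
                           utr_prob = c(long = 0.50, medium = 0.10,
                                        short = 0.02),
                           utr_meanlog = log(220), utr_sdlog = 0.5,
                           scuo_target = c(long = 0.078, medium = 0.105,
                                           short = 0.198),
                           scuo_sd = 0.03,
                           abundance_meanlog2 = log2(3000),
                           abundance_slope = 0.6,
                           abundance_sdlog2 = 1.0,
                           ts_length_slope = 0.17,
                           ts_affinity_sd = 0.05) {
  if (any(utr_prob < 0) || any(utr_prob > 1)) {
    stop("'utr_prob' entries must lie in [0, 1]", call. = FALSE)
  }
  if (any(scuo_target <= 0) || any(scuo_target >= 1)) {
    stop("'scuo_target' entries must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(meanlog = meanlog, sdlog = sdlog, length_range = length_range,
         utr_prob = utr_prob, utr_meanlog = utr_meanlog,
         utr_sdlog = utr_sdlog, scuo_target = scuo_target,
         scuo_sd = scuo_sd, abundance_meanlog2 = abundance_meanlog2,
         abundance_slope = abundance_slope,
         abundance_sdlog2 = abundance_sdlog2,
         ts_length_slope = ts_length_slope,
         ts_affinity_sd = ts_affinity_sd),
    class = "catalog_params"
  )
}

# Synonymous codon families of the standard nuclear code, Met/Trp/stop
# excluded (no synonymous choice to order).
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  fam <- split(names(gc), unname(gc))
  fam[["*"]] <- NULL
  fam[["M"]] <- NULL
  fam[["W"]] <- NULL
  fam
}

# Normalized entropy deviation of the "one preferred codon" family
# distribution p = (w, (1-w)/(n-1), ...): O(w) = 1 - H(p)/log(n).
# Monotone in w on [1/n, 1]; inverted on a dense grid.
scuo_bias_weight <- function(target, n) {
  w <- seq(1 / n, 1 - 1e-9, length.out = 512)
  h <- -(w * log(w) + (1 - w) * log(pmax((1 - w) / (n - 1), 1e-300)))
  o <- 1 - h / log(n)
  stats::approx(o, w, xout = pmin(pmax(target, 0), 1 - 1e-9),
                rule = 2)$y
}

#' Generate a synthetic gene catalog
#'
#' Draws `n_genes` genes with ORF length, 5'UTR presence/length, a target
#' codon-usage bias (`scuo_true`), a baseline transcript abundance
#' negatively correlated with length, and a coding sequence whose codons
#' are sampled so that each synonymous family's usage matches the gene's
#' bias level (one preferred codon per family, remaining mass uniform).
#'
#' @param n_genes Number of genes (>= 12).
#' @param params A [catalog_params()] object.
#' @param seed Integer seed; identical seed and parameters give a
#'   byte-identical catalog.
#' @return A data.frame of class `gene_catalog` with columns `gene_id`,
#'   `orf_length`, `utr5_length` (0 = no 5'UTR), `scuo_true`,
#'   `baseline_abundance`, `polysome_affinity`, `length_group`, `cds`.
#' @export
#' @examples
#' cat6k <- generate_gene_catalog(200, seed = 1)
#' mean(cat6k$orf_length)
generate_gene_catalog <- function(n_genes, params = catalog_params(),
                                  seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 12) {
    stop("'n_genes' must be a positive integer >= 12", call. = FALSE)
  }
  n_genes <- as.integer(n_genes)
  with_seed(child_seed(seed, "catalog"), {
    lo <- params$length_range[1]
    hi <- params$length_range[2]
    # rejection-sample the truncated log-normal (tail mass is tiny)
    len <- numeric(0)
    while (length(len) < n_genes) {
      cand <- rlnorm(n_genes, params$meanlog, params$sdlog)
      len <- c(len, cand[cand >= lo & cand <= hi])
    }
    len <- len[seq_len(n_genes)]
    # ORF length must hold full codons: round to a multiple of 3
    len <- pmax(3 * round(len / 3), 141L)
    groups <- assign_length_groups(len)

    has_utr <- rbinom(n_genes, 1, params$utr_prob[as.character(groups)])
    utr_len <- ifelse(
      has_utr == 1,
      pmax(round(rlnorm(n_genes, params$utr_meanlog, params$utr_sdlog)),
           10),
      0L
    )

    scuo_true <- pmin(pmax(
      rnorm(n_genes, params$scuo_target[as.character(groups)],
            params$scuo_sd),
      0.01), 0.95)

    log2_ab <- params$abundance_meanlog2 -
      params$abundance_slope * (log2(len) - log2(1203)) +
      rnorm(n_genes, 0, params$abundance_sdlog2)
    baseline <- 2^log2_ab

    # gene-level polysome affinity: short transcripts are relatively
    # polysome-enriched, long ones depleted, across every condition
    affinity <- 2^(-params$ts_length_slope *
                     (log2(len) - log2(1203)) +
                   rnorm(n_genes, 0, params$ts_affinity_sd))

    cds <- sample_cds(len, scuo_true)

    out <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      orf_length = as.integer(len),
      utr5_length = as.integer(utr_len),
      scuo_true = scuo_true,
      baseline_abundance = baseline,
      polysome_affinity = affinity,
      length_group = as.character(groups),
      cds = cds,
      stringsAsFactors = FALSE
    )
    class(out) <- c("gene_catalog", "data.frame")
    out
  })
}

# Vectorized codon sampling across the whole catalog: every internal
# codon is drawn from its amino acid's family with the gene's bias
# weight; start ATG and stop TAA frame the ORF.
sample_cds <- function(lengths, scuo_true) {
  fams <- codon_families()
  fam_n <- vapply(fams, length, integer(1))
  aas <- names(fams)
  n_genes <- length(lengths)
  n_internal <- lengths / 3 - 2L
  gene_idx <- rep.int(seq_len(n_genes), n_internal)
  total <- length(gene_idx)

  aa_draw <- sample(aas, total, replace = TRUE)
  codon <- character(total)
  # per-degeneracy bias weight per gene, computed once per family size
  w_by_n <- lapply(sort(unique(fam_n)), function(n) {
    scuo_bias_weight(scuo_true, n)
  })
  names(w_by_n) <- as.character(sort(unique(fam_n)))

  u <- runif(total)
  for (aa in aas) {
    idx <- which(aa_draw == aa)
    if (!length(idx)) next
    n <- fam_n[[aa]]
    w <- w_by_n[[as.character(n)]][gene_idx[idx]]
    preferred <- u[idx] < w
    alt <- 1L + sample.int(n - 1L, length(idx), replace = TRUE)
    rank <- ifelse(preferred, 1L, alt)
    codon[idx] <- fams[[aa]][rank]
  }
  body <- vapply(split(codon, factor(gene_idx, levels = seq_len(n_genes))),
                 paste, character(1), collapse = "")
  paste0("ATG", body, "TAA")
}

#' Default four-condition experimental design
#'
#' Excess glucose (D, the control), excess glycerol (G), methanol feed
#' (M) and limiting glucose (X).
#'
#' @return data.frame with columns `condition` and `control`.
#' @export
default_design <- function() {
  data.frame(
    condition = c("D", "G", "M", "X"),
    control = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Effect-size parameters for the ground truth
#'
#' Defaults emulate the study's scale of regulation: few genes change
#' transcriptionally on glycerol vs glucose, many under methanol and
#' limiting glucose; translational-state changes are rarer still, with
#' glycerol showing only a handful. Condition-level P:M ratios follow
#' the observed ordering (limiting glucose lowest, methanol highest).
#'
#' @param de_fraction Named fraction of genes with a transcriptional
#'   effect per non-control condition (unnamed scalar = same for all).
#' @param de_log2fc_range Magnitude range of spiked |log2FC|, signs
#'   drawn symmetrically.
#' @param ts_fraction Fraction of genes with a translational-state
#'   effect, as for `de_fraction`.
#' @param ts_fold_range Enriched TS fold range; depleted genes get the
#'   reciprocal.
#' @param pm_ratio Named condition-level polysome:monosome area ratios.
#' @return List of class `effect_params`.
#' @export
effect_params <- function(de_fraction = c(G = 0.05, M = 0.16, X = 0.55),
                          de_log2fc_range = c(0.6, 3),
                          ts_fraction = c(G = 0.003, M = 0.03, X = 0.03),
                          ts_fold_range = c(1.5, 3),
                          pm_ratio = c(D = 1.6, G = 2.1, M = 2.6,
                                       X = 0.7)) {
  if (any(de_fraction < 0 | de_fraction > 1) ||
      any(ts_fraction < 0 | ts_fraction > 1)) {
    stop("effect fractions must lie in [0, 1]", call. = FALSE)
  }
  if (ts_fold_range[1] < 1.5) {
    stop("enriched TS folds must be >= 1.5", call. = FALSE)
  }
  structure(
    list(de_fraction = de_fraction, de_log2fc_range = de_log2fc_range,
         ts_fraction = ts_fraction, ts_fold_range = ts_fold_range,
         pm_ratio = pm_ratio),
    class = "effect_params"
  )
}

resolve_fraction <- function(frac, conditions) {
  if (is.null(names(frac))) {
    setNames(rep_len(frac, length(conditions)), conditions)
  } else {
    out <- frac[conditions]
    if (anyNA(out)) {
      stop("effect fraction missing for condition(s): ",
           paste(conditions[is.na(out)], collapse = ", "), call. = FALSE)
    }
    out
  }
}

#' Generate ground truth for a synthetic experiment
#'
#' Assigns per-gene transcriptional log2 fold changes (vs the control
#' condition) and true translational states (1 = unchanged; enriched
#' >= 1.5-fold or depleted <= 1/1.5) to configurable fractions of genes,
#' plus condition-level true P:M ratios.
#'
#' @param catalog A [generate_gene_catalog()] result.
#' @param design data.frame with `condition` and `control` columns;
#'   exactly one control.
#' @param effects An [effect_params()] object.
#' @param seed Integer seed.
#' @return List of class `ground_truth`: `design`, matrices `log2fc` and
#'   `ts` (genes x conditions), and `pm_ratio`.
#' @export
generate_ground_truth <- function(catalog, design = default_design(),
                                  effects = effect_params(), seed = 1L) {
  if (sum(design$control) != 1) {
    stop("exactly one control condition required", call. = FALSE)
  }
  conds <- design$condition
  ctrl <- conds[design$control]
  noncontrol <- setdiff(conds, ctrl)
  n <- nrow(catalog)
  pm <- effects$pm_ratio[conds]
  if (anyNA(pm) || any(pm <= 0)) {
    stop("pm_ratio must be positive and name every condition",
         call. = FALSE)
  }
  de_frac <- resolve_fraction(effects$de_fraction, noncontrol)
  ts_frac <- resolve_fraction(effects$ts_fraction, noncontrol)

  with_seed(child_seed(seed, "truth"), {
    log2fc <- matrix(0, n, length(conds),
                     dimnames = list(catalog$gene_id, conds))
    ts <- matrix(1, n, length(conds),
                 dimnames = list(catalog$gene_id, conds))
    for (cc in noncontrol) {
      n_de <- round(de_frac[[cc]] * n)
      if (n_de > 0) {
        idx <- sample.int(n, n_de)
        mag <- runif(n_de, effects$de_log2fc_range[1],
                     effects$de_log2fc_range[2])
        log2fc[idx, cc] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
      }
      n_ts <- round(ts_frac[[cc]] * n)
      if (n_ts > 0) {
        idx <- sample.int(n, n_ts)
        fold <- exp(runif(n_ts, log(effects$ts_fold_range[1]),
                          log(effects$ts_fold_range[2])))
        flip <- runif(n_ts) < 0.5
        fold[flip] <- 1 / fold[flip]
        ts[idx, cc] <- fold
      }
    }
    structure(
      list(design = design, log2fc = log2fc, ts = ts,
           pm_ratio = setNames(as.numeric(pm), conds)),
      class = "ground_truth"
    )
  })
}

#' Simulate pool abundances (total / monosome / polysome)
#'
#' For each gene, condition and replicate: the total-mRNA abundance is
#' the baseline times the transcriptional fold change times log-normal
#' replicate noise; the polysome share of the total is the condition's
#' polysome share s_c = pm/(1+pm) scaled multiplicatively by the gene's
#' polysome affinity (a length-linked property of the transcript) and
#' its true condition-relative translational state (clipped at 0.99 so
#' the monosome pool stays positive); the monosome pool is the
#' remainder. The mixing identity
#' total = monosome + polysome therefore holds exactly before any
#' measurement noise.
#'
#' @param truth A [generate_ground_truth()] result.
#' @param catalog The matching catalog.
#' @param n_replicates Biological replicates per condition.
#' @param noise_sd Natural-log SD of replicate noise on the total pool.
#' @param seed Integer seed.
#' @return List of class `pool_abundances`: `abundance` (genes x
#'   samples), `samples` metadata (`sample_id`, `condition`,
#'   `replicate`, `fraction`).
#' @export
simulate_fraction_abundances <- function(truth, catalog,
                                         n_replicates = 3,
                                         noise_sd = 0.25, seed = 1L) {
  if (!identical(rownames(truth$log2fc), catalog$gene_id)) {
    stop("truth and catalog gene ids disagree", call. = FALSE)
  }
  conds <- truth$design$condition
  n <- nrow(catalog)
  s_c <- truth$pm_ratio / (1 + truth$pm_ratio)

  samples <- expand.grid(
    fraction = c("total", "monosome", "polysome"),
    replicate = seq_len(n_replicates),
    condition = conds,
    stringsAsFactors = FALSE
  )[, 3:1]
  samples$sample_id <- with(samples,
                            paste(condition, replicate, fraction,
                                  sep = "."))

  with_seed(child_seed(seed, "abundances"), {
    abund <- matrix(NA_real_, n, nrow(samples),
                    dimnames = list(catalog$gene_id, samples$sample_id))
    n_clipped <- 0L
    affinity <- if (!is.null(catalog[["polysome_affinity"]])) {
      catalog[["polysome_affinity"]]
    } else rep(1, n)
    for (cc in conds) {
      share <- s_c[[cc]] * affinity * truth$ts[, cc]
      clipped <- share >= 0.99
      n_clipped <- n_clipped + sum(clipped)
      share <- pmin(share, 0.99)
      for (r in seq_len(n_replicates)) {
        total <- catalog$baseline_abundance * 2^truth$log2fc[, cc] *
          exp(rnorm(n, 0, noise_sd))
        poly <- total * share
        mono <- total - poly
        abund[, paste(cc, r, "total", sep = ".")] <- total
        abund[, paste(cc, r, "monosome", sep = ".")] <- mono
        abund[, paste(cc, r, "polysome", sep = ".")] <- poly
      }
    }
    if (n_clipped > 0) {
      warning(sprintf(
        "%d gene x condition polysome shares clipped at 0.99", n_clipped))
    }
    structure(
      list(abundance = abund,
           samples = samples[, c("sample_id", "condition", "replicate",
                                 "fraction")]),
      class = "pool_abundances"
    )
  })
}

#' Build the dye-swap hybridization sample sheet
#'
#' Every (condition, replicate, fraction) RNA sample is hybridized twice
#' against the common reference pool, once in each dye orientation.
#'
#' @param design Experimental design as in [default_design()].
#' @param n_replicates Biological replicates per condition.
#' @param fractions RNA pools hybridized.
#' @return data.frame of class `sample_sheet` with columns `array_id`,
#'   `condition`, `replicate`, `fraction`, `dye_orientation`.
#' @export
make_sample_sheet <- function(design = default_design(),
                              n_replicates = 3,
                              fractions = c("total", "monosome",
                                            "polysome")) {
  base <- expand.grid(
    dye_orientation = c("sample_red", "sample_green"),
    fraction = fractions,
    replicate = seq_len(n_replicates),
    condition = design$condition,
    stringsAsFactors = FALSE
  )[, 4:1]
  base$array_id <- sprintf("A%03d", seq_len(nrow(base)))
  out <- base[, c("array_id", "condition", "replicate", "fraction",
                  "dye_orientation")]
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Array bias parameters
#'
#' @param scale_sd Natural-log SD of the per-array intensity scale.
#' @param dye_coef Coefficients (c0, c1, c2) of the dye bias added to
#'   the red-green log2 ratio as c0 + c1 z + c2 z^2, with z the
#'   within-array standardized average log intensity A. The bias follows
#'   the dye, so dye-swap pairs see it with opposite sign relative to
#'   the sample.
#' @param noise_sd Natural-log SD of multiplicative per-channel
#'   measurement noise.
#' @return List of class `bias_params`.
#' @export
bias_params <- function(scale_sd = 0.15,
                        dye_coef = c(0.15, 0.15, 0.15),
                        noise_sd = 0.10) {
  structure(list(scale_sd = scale_sd, dye_coef = dye_coef,
                 noise_sd = noise_sd),
            class = "bias_params")
}

#' Simulate raw two-channel array intensities
#'
#' The reference channel carries the pooled mean abundance over all
#' samples; the sample channel carries the sample's pool abundance.
#' A per-array multiplicative scale, a smooth intensity-dependent dye
#' bias on the log ratio (default quadratic in A), and multiplicative
#' log-normal measurement noise are applied. All intensities are
#' strictly positive; no background model (raw, background-free
#' intensities).
#'
#' @param abund A [simulate_fraction_abundances()] result.
#' @param sheet A [make_sample_sheet()] result consistent with `abund`.
#' @param bias A [bias_params()] object.
#' @param seed Integer seed.
#' @return List of class `intensity_matrix`: matrices `red` and `green`
#'   (genes x arrays), `genes`, and the `sheet`.
#' @export
simulate_arrays <- function(abund, sheet, bias = bias_params(),
                            seed = 1L) {
  key <- paste(sheet$condition, sheet$replicate, sheet$fraction,
               sep = ".")
  if (!all(key %in% colnames(abund$abundance))) {
    stop("sample sheet refers to samples absent from the abundance table",
         call. = FALSE)
  }
  genes <- rownames(abund$abundance)
  n <- length(genes)
  ref <- rowMeans(abund$abundance)

  with_seed(child_seed(seed, "arrays"), {
    red <- green <- matrix(NA_real_, n, nrow(sheet),
                           dimnames = list(genes, sheet$array_id))
    for (i in seq_len(nrow(sheet))) {
      s <- abund$abundance[, key[i]]
      k <- exp(rnorm(1, 0, bias$scale_sd))
      m0 <- log2(s / ref)
      a <- 0.5 * log2(s * ref)
      z <- (a - mean(a)) / sd(a)
      g <- bias$dye_coef[1] + bias$dye_coef[2] * z +
        bias$dye_coef[3] * z^2
      sgn <- if (sheet$dye_orientation[i] == "sample_red") 1 else -1
      lr <- sgn * m0 + g   # log2(red/green) on this array
      red[, i] <- k * sqrt(s * ref) * 2^(lr / 2) *
        exp(rnorm(n, 0, bias$noise_sd))
      green[, i] <- k * sqrt(s * ref) * 2^(-lr / 2) *
        exp(rnorm(n, 0, bias$noise_sd))
    }
    structure(list(red = red, green = green, genes = genes,
                   sheet = sheet),
              class = "intensity_matrix")
  })
}

#' Trace simulation parameters
#'
#' @param n_points Grid points along the gradient.
#' @param x_max Gradient depth span (arbitrary units).
#' @param mono_area Area of the 80S (monosome) peak.
#' @param sub_areas Areas of the 40S and 60S subunit peaks.
#' @param peak_pos Positions of the 40S, 60S and 80S peaks.
#' @param peak_width SDs of the 40S, 60S, 80S Gaussian peaks.
#' @param n_poly Number of resolvable polysome peaks (>= 3).
#' @param poly_start,poly_spacing Position of the first polysome peak
#'   and spacing between successive ones.
#' @param poly_width_base,poly_width_step Width of the first polysome
#'   peak and per-peak broadening along the gradient.
#' @param poly_decay Geometric decay of successive polysome peak areas.
#' @param baseline Intercept and slope of the linear baseline drift.
#' @param noise_sd SD of additive white noise on the absorbance.
#' @return List of class `trace_params`.
#' @export
trace_params <- function(n_points = 1200, x_max = 100, mono_area = 1,
                         sub_areas = c(0.25, 0.35),
                         peak_pos = c(12, 20, 30),
                         peak_width = c(1.6, 1.8, 2.0),
                         n_poly = 5, poly_start = 42, poly_spacing = 9,
                         poly_width_base = 2.4, poly_width_step = 0.25,
                         poly_decay = 0.65,
                         baseline = c(0.02, 0.0008),
                         noise_sd = 0.004) {
  if (n_poly < 3) stop("at least 3 polysome peaks required", call. = FALSE)
  structure(
    list(n_points = n_points, x_max = x_max, mono_area = mono_area,
         sub_areas = sub_areas, peak_pos = peak_pos,
         peak_width = peak_width, n_poly = n_poly,
         poly_start = poly_start, poly_spacing = poly_spacing,
         poly_width_base = poly_width_base,
         poly_width_step = poly_width_step, poly_decay = poly_decay,
         baseline = baseline, noise_sd = noise_sd),
    class = "trace_params"
  )
}

#' Simulate an A254 polysome-gradient trace
#'
#' Builds a gradient absorbance trace as a linear baseline drift plus
#' Gaussian peaks for the 40S and 60S subunits, the 80S monosome, and
#' `n_poly` polysome peaks whose areas decay geometrically along the
#' gradient, plus additive white noise. In the noise-free construction
#' the summed polysome area divided by the 80S area equals `pm_ratio`
#' exactly; the true component areas are returned for oracle tests.
#'
#' @param pm_ratio True polysome:monosome area ratio (> 0).
#' @param params A [trace_params()] object.
#' @param seed Integer seed.
#' @return List of class `simulated_trace`: `trace` (a `profile_trace`),
#'   and `truth` (true areas, pm_ratio, peak positions).
#' @export
simulate_profile_trace <- function(pm_ratio, params = trace_params(),
                                   seed = 1L) {
  stop_if_not_scalar_pos(pm_ratio, "pm_ratio")
  k <- params$n_poly
  x <- seq(0, params$x_max, length.out = params$n_points)
  w_poly <- params$poly_width_base +
    params$poly_width_step * (seq_len(k) - 1)
  pos_poly <- params$poly_start + params$poly_spacing * (seq_len(k) - 1)
  rel <- params$poly_decay^(seq_len(k) - 1)
  a_poly <- rel / sum(rel) * pm_ratio * params$mono_area

  areas <- c(params$sub_areas, params$mono_area, a_poly)
  pos <- c(params$peak_pos, pos_poly)
  wid <- c(params$peak_width, w_poly)

  signal_y <- rowSums(vapply(seq_along(areas), function(i) {
    areas[i] * dnorm(x, pos[i], wid[i])
  }, numeric(length(x))))
  base_y <- params$baseline[1] + params$baseline[2] * x

  with_seed(child_seed(seed, "trace"), {
    y <- base_y + signal_y + rnorm(length(x), 0, params$noise_sd)
    trace <- new_profile_trace(x, y)
    truth <- list(
      pm_ratio = pm_ratio,
      areas = c(`40S` = areas[1], `60S` = areas[2],
                monosome = areas[3], polysome = sum(a_poly)),
      peak_positions = setNames(pos, c("40S", "60S", "monosome",
                                       paste0("poly", seq_len(k))))
    )
    structure(list(trace = trace, truth = truth),
              class = "simulated_trace")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  ctrl <- x$design$condition[x$design$control]
  cat("Ground truth:", nrow(x$log2fc), "genes x",
      ncol(x$log2fc), "conditions (control:", ctrl, ")\n")
  cat("  transcriptional effects:",
      sum(x$log2fc != 0), "gene x condition cells\n")
  cat("  translational effects:  ",
      sum(x$ts != 1), "gene x condition cells\n")
  cat("  P:M:", paste(sprintf("%s=%.2f", names(x$pm_ratio), x$pm_ratio),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("Two-channel intensities:", length(x$genes), "genes x",
      ncol(x$red), "arrays\n")
  invisible(x)
}
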