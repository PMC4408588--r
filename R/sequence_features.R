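# ORF-feature analysis: synonymous codon usage order (SCUO), the
# fixed-length gene groups, per-group summary statistics and the
# association-test battery linking length, expression, translational
# state, 5'UTR frequency and codon bias.

#' Synonymous codon usage order (SCUO) of a coding sequence
#'
#' Entropy-based 0-1 measure of codon-usage bias. For each degenerate
#' amino acid i with n_i synonymous codons used with frequencies p_ij,
#' the normalized entropy deviation is
#' O_i = (log n_i - H_i) / log n_i with H_i = -sum_j p_ij log p_ij,
#' and SCUO = sum_i F_i O_i, where F_i is amino acid i's frequency
#' among all degenerate-amino-acid occurrences in the sequence.
#' Methionine, tryptophan and stop codons are excluded (no synonymous
#' choice). 1 = maximal bias (one codon per amino acid), 0 = perfectly
#' uniform synonymous usage. Natural logarithms are used; the ratio
#' normalization makes the value base-independent.
#'
#' @param cds Nucleotide string(s); length must be divisible by 3.
#' @param ambiguity `"error"` (default) rejects ambiguous bases,
#'   `"skip"` drops codons containing them.
#' @return Numeric SCUO value(s) in [0, 1].
#' @export
#' @examples
#' compute_scuo(strrep("GGCGAA", 30)) # single codon per amino acid: 1
compute_scuo <- function(cds, ambiguity = c("error", "skip")) {
  ambiguity <- match.arg(ambiguity)
  n_seq <- length(cds)
  cds <- toupper(cds)
  nc <- nchar(cds)
  if (any(nc %% 3 != 0)) {
    stop("CDS length not divisible by 3", call. = FALSE)
  }
  # one flat codon stream over all sequences, tabulated per sequence
  n_codons <- nc / 3
  seq_idx <- rep.int(seq_len(n_seq), n_codons)
  flat <- paste(cds, collapse = "")
  starts <- seq(1, nchar(flat) - 2, 3)
  codons <- substring(flat, starts, starts + 2)

  all_codons <- names(Biostrings::GENETIC_CODE)
  code <- match(codons, all_codons)
  if (anyNA(code)) {
    if (ambiguity == "error") {
      stop("ambiguous bases in CDS (set ambiguity = \"skip\" to drop)",
           call. = FALSE)
    }
    keep <- !is.na(code)
    code <- code[keep]; seq_idx <- seq_idx[keep]
  }
  counts <- matrix(
    tabulate((seq_idx - 1L) * 64L + code, nbins = n_seq * 64L),
    nrow = n_seq, ncol = 64L, byrow = TRUE,
    dimnames = list(NULL, all_codons)
  )

  fam <- codon_families()
  deg_codons <- unlist(fam, use.names = FALSE)
  total_deg <- rowSums(counts[, deg_codons, drop = FALSE])
  if (any(total_deg == 0)) {
    stop("no degenerate amino acids in sequence", call. = FALSE)
  }
  scuo <- numeric(n_seq)
  for (a in names(fam)) {
    cc <- counts[, fam[[a]], drop = FALSE]
    n_a <- rowSums(cc)
    present <- n_a > 0
    if (!any(present)) next
    p <- cc[present, , drop = FALSE] / n_a[present]
    h <- -rowSums(ifelse(p > 0, p * log(p), 0))
    n_i <- length(fam[[a]])
    o <- (log(n_i) - h) / log(n_i)
    scuo[present] <- scuo[present] +
      (n_a[present] / total_deg[present]) * o
  }
  scuo
}

#' Assign ORF-length groups
#'
#' Labels genes long / medium / short. In the fixed (annotation-
#' faithful) mode, long means length > 1807 bp, short means
#' length < 770 bp, medium otherwise (boundary values are medium);
#' these cutoffs are the upper/lower quartiles of the *P. pastoris*
#' annotation. In quantile mode the 25%/75% quantiles of the input
#' lengths are used instead.
#'
#' @param lengths Positive integer vector of ORF lengths (bp).
#' @param cutoffs `(short, long)` cutoff pair, default `c(770, 1807)`.
#' @param mode `"fixed"` or `"quantile"`.
#' @return Factor with levels long, medium, short.
#' @export
#' @examples
#' assign_length_groups(c(2412, 1203, 540))
assign_length_groups <- function(lengths, cutoffs = c(770, 1807),
                                 mode = c("fixed", "quantile")) {
  mode <- match.arg(mode)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (mode == "quantile") {
    cutoffs <- unname(quantile(lengths, c(0.25, 0.75)))
  }
  factor(ifelse(lengths > cutoffs[2], "long",
                ifelse(lengths < cutoffs[1], "short", "medium")),
         levels = c("long", "medium", "short"))
}

#' Per-gene expression intensity from raw arrays
#'
#' Mean sample-channel intensity over the arrays of one RNA fraction.
#' Between-gene expression comparisons need the intensity scale: the
#' normalized log2 ratios are relative to the common reference pool
#' per gene and carry no between-gene information.
#'
#' @param im An `intensity_matrix`.
#' @param fraction RNA fraction to average over.
#' @return Named numeric vector of per-gene mean intensities.
#' @export
expression_intensity <- function(im, fraction = "total") {
  sheet <- im$sheet
  keep <- sheet$fraction == fraction
  if (!any(keep)) stop("no arrays of fraction ", fraction, call. = FALSE)
  sample_int <- ifelse(
    rep(sheet$dye_orientation == "sample_red", each = nrow(im$red)),
    im$red, im$green)
  dim(sample_int) <- dim(im$red)
  rowMeans(sample_int[, keep, drop = FALSE]) |>
    setNames(im$genes)
}

# Resolve the expression argument: a numeric per-gene vector (intensity
# scale), an intensity_matrix, or NULL (catalog baseline abundance).
resolve_expression <- function(expr, catalog) {
  if (is.null(expr)) return(catalog[["baseline_abundance"]])
  if (inherits(expr, "intensity_matrix")) {
    return(unname(expression_intensity(expr)[catalog$gene_id]))
  }
  if (is.numeric(expr)) {
    v <- if (!is.null(names(expr))) expr[catalog$gene_id] else expr
    return(unname(v))
  }
  stop("'expr' must be a per-gene intensity vector or an intensity_matrix",
       call. = FALSE)
}

#' Length-group summary statistics
#'
#' Per length group: gene count, mean/median ORF length, mean/median
#' expression intensity, mean/median SCUO, count and percentage of
#' genes with a 5'UTR, mean 5'UTR length, and mean translational state
#' (mean log_ts of the chosen condition, or averaged over conditions).
#'
#' @param catalog A `gene_catalog` (columns `orf_length`,
#'   `utr5_length`; `scuo` is computed from `cds` unless a `scuo`
#'   column is present).
#' @param expr Per-gene expression intensities: a numeric vector or an
#'   `intensity_matrix` (total-fraction sample-channel mean); `NULL`
#'   falls back to the catalog's baseline abundance.
#' @param ts Optional `ts_table` for translational states.
#' @param groups Optional precomputed group factor; custom factors
#'   (e.g. a single level) are summarized per level. Every level must
#'   be populated.
#' @return data.frame of class `group_stats`, one row per group plus a
#'   whole-catalog row.
#' @export
summarize_groups <- function(catalog, expr = NULL, ts = NULL,
                             groups = NULL) {
  if (is.null(groups)) groups <- assign_length_groups(catalog$orf_length)
  scuo <- if (!is.null(catalog[["scuo"]])) {
    catalog[["scuo"]]
  } else if (!is.null(catalog[["cds"]])) {
    compute_scuo(catalog[["cds"]])
  } else {
    catalog[["scuo_true"]]
  }
  expr_int <- resolve_expression(expr, catalog)
  mean_ts <- if (!is.null(ts)) {
    rowMeans(ts$mean_log_ts)[catalog$gene_id]
  } else NULL

  one <- function(idx, label) {
    if (!length(idx)) stop("empty length group: ", label, call. = FALSE)
    data.frame(
      group = label,
      n_genes = length(idx),
      mean_orf_length = mean(catalog$orf_length[idx]),
      median_orf_length = median(catalog$orf_length[idx]),
      mean_expression = if (is.null(expr_int)) NA_real_ else
        mean(expr_int[idx]),
      median_expression = if (is.null(expr_int)) NA_real_ else
        median(expr_int[idx]),
      mean_scuo = mean(scuo[idx]),
      median_scuo = median(scuo[idx]),
      n_utr5 = sum(catalog$utr5_length[idx] > 0),
      pct_utr5 = 100 * mean(catalog$utr5_length[idx] > 0),
      mean_utr5_length = if (any(catalog$utr5_length[idx] > 0))
        mean(catalog$utr5_length[idx][catalog$utr5_length[idx] > 0])
      else NA_real_,
      mean_translational_state = if (is.null(mean_ts)) NA_real_ else
        mean(mean_ts[idx]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(
    lapply(levels(groups), function(g) one(which(groups == g), g)),
    list(one(seq_len(nrow(catalog)), "all"))
  ))
  class(out) <- c("group_stats", "data.frame")
  out
}

#' Association-test battery for ORF features
#'
#' Runs the relationships between ORF length and the other gene
#' features, all two-sided:
#' \itemize{
#'   \item linear regression of log2 expression on ORF length
#'     (negative slope expected: short genes are more highly
#'     expressed);
#'   \item rank (Spearman) association of SCUO with length, plus an
#'     exponential-decay least-squares fit
#'     SCUO ~ a exp(-length/L) + c;
#'   \item linear regression of mean log translational state on
#'     length;
#'   \item Fisher exact and chi-square tests of 5'UTR presence x
#'     length group (long vs short for the 2x2 Fisher; full 2x3 for
#'     chi-square);
#'   \item Shapiro-Wilk normality per group (on SCUO), then pairwise
#'     Wilcoxon rank tests between groups.
#' }
#'
#' @param catalog A `gene_catalog`.
#' @param expr Per-gene expression intensities as in
#'   [summarize_groups()].
#' @param ts Optional `ts_table`.
#' @param groups Optional precomputed group factor.
#' @return data.frame of class `association_tests`: `test`,
#'   `statistic`, `estimate`, `p_value`.
#' @export
association_tests <- function(catalog, expr = NULL, ts = NULL,
                              groups = NULL) {
  if (nrow(catalog) < 20) {
    stop("association tests need >= 20 genes", call. = FALSE)
  }
  if (is.null(groups)) groups <- assign_length_groups(catalog$orf_length)
  len <- catalog$orf_length
  scuo <- if (!is.null(catalog[["cds"]])) {
    compute_scuo(catalog[["cds"]])
  } else {
    catalog[["scuo_true"]]
  }
  expr_val <- log2(resolve_expression(expr, catalog))
  rows <- list()
  add <- function(test, statistic, estimate, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      test = test, statistic = statistic, estimate = estimate,
      p_value = p, stringsAsFactors = FALSE)
  }

  fit <- lm(expr_val ~ len)
  sm <- summary(fit)
  add("expression_vs_length_lm", sm$coefficients[2, 3],
      sm$coefficients[2, 1], sm$coefficients[2, 4])

  ct <- suppressWarnings(cor.test(scuo, len, method = "spearman"))
  add("scuo_vs_length_spearman", unname(ct$statistic),
      unname(ct$estimate), ct$p.value)
  expfit <- tryCatch({
    nf <- nls(scuo ~ a * exp(-len / L) + c0,
              start = list(a = max(scuo) - min(scuo), L = 1500,
                           c0 = min(scuo)),
              control = list(warnOnly = TRUE))
    cf <- summary(nf)$coefficients
    add("scuo_vs_length_expdecay", cf["a", 3], cf["a", 1],
        cf["a", 4])
    TRUE
  }, error = function(e) FALSE)

  if (!is.null(ts)) {
    mean_ts <- rowMeans(ts$mean_log_ts)[catalog$gene_id]
    fit_ts <- lm(mean_ts ~ len)
    sm_ts <- summary(fit_ts)
    add("ts_vs_length_lm", sm_ts$coefficients[2, 3],
        sm_ts$coefficients[2, 1], sm_ts$coefficients[2, 4])
  }

  has_utr <- catalog$utr5_length > 0
  tab2 <- table(utr = has_utr[groups != "medium"],
                group = droplevels(groups[groups != "medium"]))
  if (all(dim(tab2) == c(2, 2))) {
    ft <- fisher.test(tab2)
    add("utr_vs_length_group_fisher", NA_real_,
        unname(ft$estimate), ft$p.value)
  }
  tab3 <- table(utr = has_utr, group = groups)
  if (all(colSums(tab3) > 0)) {
    cs <- suppressWarnings(chisq.test(tab3))
    add("utr_vs_length_group_chisq", unname(cs$statistic), NA_real_,
        cs$p.value)
  }

  for (g in levels(groups)) {
    v <- scuo[groups == g]
    if (length(v) >= 3) {
      v_sw <- if (length(v) > 5000) sample(v, 5000) else v
      sw <- shapiro.test(v_sw)
      add(paste0("scuo_shapiro_", g), unname(sw$statistic), NA_real_,
          sw$p.value)
    }
  }
  pairs <- list(c("long", "medium"), c("long", "short"),
                c("medium", "short"))
  for (pr in pairs) {
    wt <- wilcox.test(scuo[groups == pr[1]], scuo[groups == pr[2]])
    add(paste0("scuo_wilcoxon_", pr[1], "_vs_", pr[2]),
        unname(wt$statistic), NA_real_, wt$p.value)
  }

  out <- do.call(rbind, rows)
  class(out) <- c("association_tests", "data.frame")
  out
}
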