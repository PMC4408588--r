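# The per-transcript translational state: the abundance of a
# transcript in the polysome fraction normalized to its abundance in
# total RNA, computed on log2 ratios vs the common reference so that
# reference and array effects cancel. Changes vs the control condition
# define translational enrichment/depletion.

#' Compute absolute translational states
#'
#' Per gene, condition and replicate: log_ts = (polysome log2 ratio) -
#' (total log2 ratio). Transcriptional changes affect both fractions
#' equally and cancel, so log_ts isolates the translational component.
#'
#' @param expr An `expr_table` with matched `total` and `polysome`
#'   columns per (condition, replicate).
#' @return List of class `ts_table`: `log_ts` (genes x
#'   condition.replicate), `samples` metadata, and `mean_log_ts`
#'   (genes x condition).
#' @export
compute_translational_state <- function(expr) {
  samp <- expr$samples
  need <- c("total", "polysome")
  if (!all(need %in% samp$fraction)) {
    stop("expression table must contain total and polysome fractions",
         call. = FALSE)
  }
  tot <- samp[samp$fraction == "total", ]
  pol <- samp[samp$fraction == "polysome", ]
  key_t <- paste(tot$condition, tot$replicate, sep = ".")
  key_p <- paste(pol$condition, pol$replicate, sep = ".")
  common <- intersect(key_t, key_p)
  if (!length(common)) {
    stop("no matched (condition, replicate) total/polysome pairs",
         call. = FALSE)
  }
  missing_t <- setdiff(key_p, key_t)
  missing_p <- setdiff(key_t, key_p)
  if (length(missing_t) || length(missing_p)) {
    stop("unmatched fraction columns for: ",
         paste(c(missing_t, missing_p), collapse = ", "), call. = FALSE)
  }
  log_ts <- expr$E[, pol$sample_id[match(common, key_p)], drop = FALSE] -
    expr$E[, tot$sample_id[match(common, key_t)], drop = FALSE]
  colnames(log_ts) <- common
  conds <- unique(tot$condition[match(common, key_t)])
  cond_of <- sub("\\.[^.]+$", "", common)
  mean_log_ts <- vapply(conds, function(cc) {
    rowMeans(log_ts[, cond_of == cc, drop = FALSE])
  }, numeric(nrow(log_ts)))
  samples <- data.frame(
    sample_id = common,
    condition = cond_of,
    replicate = as.integer(sub("^.*\\.", "", common)),
    stringsAsFactors = FALSE
  )
  structure(list(log_ts = log_ts, samples = samples,
                 mean_log_ts = mean_log_ts),
            class = "ts_table")
}

#' Relative translational states and enrichment/depletion calls
#'
#' Normalizes each condition's translational states to the control
#' condition: rel_ts_fold = 2^(mean log_ts condition - mean log_ts
#' control) per gene. The log_ts difference is tested with the same
#' moderated two-group machinery as the transcriptional contrasts, BH
#' adjusted across genes within each contrast, and called enriched /
#' depleted / ns by the +/-50% fold-change and adjusted-p rule.
#'
#' @param ts A [compute_translational_state()] result.
#' @param control Control condition id.
#' @param fc Linear fold cutoff (> 1), default 1.5 (+/-50%).
#' @param alpha Adjusted-p cutoff.
#' @param moderation Use empirical-Bayes variance shrinkage.
#' @return data.frame of class `ts_contrast_table`: `gene_id`,
#'   `condition`, `log_ts`, `rel_ts_fold`, `t_statistic`, `p_value`,
#'   `adj_p`, `call` in \{enriched, depleted, ns\}.
#' @export
relative_ts <- function(ts, control, fc = 1.5, alpha = 0.05,
                        moderation = TRUE) {
  if (fc <= 1) stop("'fc' must be > 1", call. = FALSE)
  samp <- ts$samples
  if (!control %in% samp$condition) {
    stop("unknown control condition: ", control, call. = FALSE)
  }
  conds <- setdiff(unique(samp$condition), control)
  mat_0 <- ts$log_ts[, samp$condition == control, drop = FALSE]
  thr <- log2(fc)
  out <- do.call(rbind, lapply(conds, function(cc) {
    mat_c <- ts$log_ts[, samp$condition == cc, drop = FALSE]
    fit <- moderated_two_group(mat_c, mat_0, moderation)
    adj <- bh_adjust(fit$p)
    data.frame(
      gene_id = rownames(ts$log_ts),
      condition = cc,
      log_ts = rowMeans(mat_c),
      rel_ts_fold = 2^fit$log2fc,
      t_statistic = fit$t,
      p_value = fit$p,
      adj_p = adj,
      call = ifelse(adj < alpha & fit$log2fc >= thr, "enriched",
                    ifelse(adj < alpha & fit$log2fc <= -thr,
                           "depleted", "ns")),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("ts_contrast_table", "data.frame")
  out
}

#' Fraction-integrity regression
#'
#' Confirms that the fractionation conserved the mRNA pool: per gene,
#' log10 of the total-RNA intensity is regressed on log10 of the sum
#' of the monosome and polysome intensities (replicate-averaged within
#' the chosen condition). Exact mixing gives R^2 = 1 with slope 1.
#'
#' @param x A `pool_abundances` (simulator output) or an
#'   `intensity_matrix` (the dye-swap-averaged sample-channel
#'   intensities are used).
#' @param condition Condition to check.
#' @return List of class `integrity_result`: `r_squared`, `slope`,
#'   `intercept`, `n`.
#' @export
fraction_integrity <- function(x, condition) {
  if (inherits(x, "pool_abundances")) {
    samp <- x$samples
    get_frac <- function(fr) {
      cols <- samp$sample_id[samp$condition == condition &
                               samp$fraction == fr]
      if (!length(cols)) {
        stop("missing ", fr, " samples for condition ", condition,
             call. = FALSE)
      }
      rowMeans(x$abundance[, cols, drop = FALSE])
    }
  } else if (inherits(x, "intensity_matrix")) {
    sheet <- x$sheet
    sample_int <- ifelse(
      rep(sheet$dye_orientation == "sample_red", each = nrow(x$red)),
      x$red, x$green
    )
    dim(sample_int) <- dim(x$red)
    colnames(sample_int) <- colnames(x$red)
    get_frac <- function(fr) {
      cols <- sheet$array_id[sheet$condition == condition &
                               sheet$fraction == fr]
      if (!length(cols)) {
        stop("missing ", fr, " arrays for condition ", condition,
             call. = FALSE)
      }
      rowMeans(sample_int[, cols, drop = FALSE])
    }
  } else {
    stop("unsupported input type", call. = FALSE)
  }
  total <- get_frac("total")
  mono <- get_frac("monosome")
  poly <- get_frac("polysome")
  if (any(total <= 0) || any(mono + poly <= 0)) {
    stop("nonpositive intensities in integrity regression",
         call. = FALSE)
  }
  fit <- lm(log10(total) ~ log10(mono + poly))
  # exact mixing gives a perfect fit; the summary warning is expected
  structure(
    list(r_squared = suppressWarnings(summary(fit)$r.squared),
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         n = length(total)),
    class = "integrity_result"
  )
}

#' @export
print.integrity_result <- function(x, ...) {
  cat(sprintf(
    "Fraction integrity: R^2 = %.3f, slope = %.3f (n = %d genes)\n",
    x$r_squared, x$slope, x$n))
  invisible(x)
}

#' @export
print.ts_table <- function(x, ...) {
  cat("Translational states:", nrow(x$log_ts), "genes x",
      ncol(x$log_ts), "condition.replicate columns\n")
  invisible(x)
}
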