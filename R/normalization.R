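# Two-colour preprocessing, in the order used for the arrays: MA
# transform, within-array loess colour normalization, dye-swap
# combination, between-array quantile normalization, PCA replicate QC.
# No background subtraction anywhere: the data are raw intensities.

new_expr_table <- function(E, samples) {
  stopifnot(ncol(E) == nrow(samples))
  colnames(E) <- samples$sample_id
  structure(list(E = E, samples = samples), class = "expr_table")
}

#' MA transform of raw two-channel intensities
#'
#' M = log2(sample/reference) and A = (1/2) log2(sample x reference)
#' per gene per array. M is orientation-corrected: positive M always
#' means the sample channel is above the common reference pool,
#' regardless of which dye carried the sample.
#'
#' @param raw An `intensity_matrix`.
#' @param sheet The matching `sample_sheet`; defaults to `raw$sheet`.
#' @return List of class `ma_values`: matrices `M` and `A` (genes x
#'   arrays) and the `sheet`.
#' @export
compute_ma <- function(raw, sheet = raw$sheet) {
  bad <- which(raw$red <= 0 | raw$green <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ex <- head(bad, 5)
    stop("non-positive intensities at (gene, array): ",
         paste(sprintf("(%s, %s)", rownames(raw$red)[ex[, 1]],
                       colnames(raw$red)[ex[, 2]]), collapse = ", "),
         if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5),
         call. = FALSE)
  }
  m_raw <- log2(raw$red / raw$green)
  a <- 0.5 * log2(raw$red * raw$green)
  sgn <- ifelse(sheet$dye_orientation[match(colnames(m_raw),
                                            sheet$array_id)] ==
                  "sample_red", 1, -1)
  m <- sweep(m_raw, 2, sgn, `*`)
  structure(list(M = m, A = a, sheet = sheet), class = "ma_values")
}

#' Within-array loess colour normalization
#'
#' Removes the intensity-dependent dye trend per array: M' = M -
#' loess(M ~ A), with a degree-1 robust ("symmetric" family) local
#' regression. The fitted trends are retained for QC.
#'
#' @param ma An [compute_ma()] result.
#' @param span Loess span in (0, 1].
#' @return An `ma_values` object with normalized `M` and a `trend`
#'   matrix of the removed fits.
#' @export
loess_normalize <- function(ma, span = 0.3) {
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]",
                                  call. = FALSE)
  if (nrow(ma$M) < 100) {
    stop("loess colour normalization needs >= 100 genes per array",
         call. = FALSE)
  }
  trend <- ma$M
  for (j in seq_len(ncol(ma$M))) {
    trend[, j] <- ma_trend_fit(ma$A[, j], ma$M[, j], span)
  }
  out <- ma
  out$M <- ma$M - trend
  out$trend <- trend
  out
}

# Robust local-linear MA trend via lowess (3 robustifying iterations),
# evaluated at every A.
ma_trend_fit <- function(a, m, span = 0.3) {
  fit <- stats::lowess(a, m, f = span, iter = 3)
  approx(fit$x, fit$y, xout = a, rule = 2, ties = "ordered")$y
}

#' Maximum absolute loess MA-trend per array (QC)
#'
#' The trend is evaluated over the interior of each array's A range
#' (`trim` quantile trimmed at both ends) so the metric reflects the
#' dye trend where probes actually sit, not the extrapolation at a
#' handful of extreme-intensity spots.
#'
#' @param ma An `ma_values` object.
#' @param span Loess span.
#' @param trim Quantile trimmed from each end of A.
#' @return Named numeric vector: per array, max |fitted M trend|.
#' @export
ma_trend_magnitude <- function(ma, span = 0.3, trim = 0.02) {
  vapply(seq_len(ncol(ma$M)), function(j) {
    a <- ma$A[, j]
    fit <- ma_trend_fit(a, ma$M[, j], span)
    qa <- quantile(a, c(trim, 1 - trim))
    max(abs(fit[a >= qa[1] & a <= qa[2]]))
  }, numeric(1)) |> setNames(colnames(ma$M))
}

#' Between-array quantile normalization
#'
#' Forces every column to the same distribution: the row-wise mean of
#' the sorted columns. Ties receive the average of their target
#' quantiles, making the map deterministic and order-independent.
#' Idempotent. Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param x Numeric matrix (genes x arrays/samples) or an `expr_table`.
#' @return Object of the same kind with normalized values.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expr_table")) {
    x$E <- quantile_normalize(x$E)
    return(x)
  }
  if (anyNA(x)) stop("missing values not supported", call. = FALSE)
  if (ncol(x) == 1) {
    warning("single column: quantile normalization is a no-op")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Combine dye-swap pairs into one log2 ratio per sample
#'
#' Each (condition, replicate, fraction) sample was hybridized twice,
#' once per dye orientation; the combined value is the mean of the two
#' orientation-corrected M values, which cancels residual dye bias and
#' halves the noise variance.
#'
#' @param ma An `ma_values` object (normally after [loess_normalize()]).
#' @param sheet The matching `sample_sheet`.
#' @param allow_unpaired If `TRUE`, samples present in only one
#'   orientation fall back to that single array; otherwise they are an
#'   error.
#' @return An `expr_table`: one column per sample, named
#'   `condition.replicate.fraction`.
#' @export
combine_dye_swaps <- function(ma, sheet = ma$sheet,
                              allow_unpaired = FALSE) {
  key <- paste(sheet$condition, sheet$replicate, sheet$fraction,
               sep = ".")
  ord <- match(colnames(ma$M), sheet$array_id)
  key <- key[ord]
  counts <- table(key)
  if (any(counts != 2) && !allow_unpaired) {
    bad <- names(counts)[counts != 2]
    stop("unpaired dye-swap sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  uk <- unique(key)
  E <- vapply(uk, function(k) rowMeans(ma$M[, key == k, drop = FALSE]),
              numeric(nrow(ma$M)))
  E <- matrix(E, nrow = nrow(ma$M),
              dimnames = list(rownames(ma$M), uk))
  parts <- strsplit(uk, ".", fixed = TRUE)
  samples <- data.frame(
    sample_id = uk,
    condition = vapply(parts, `[`, character(1), 1),
    replicate = as.integer(vapply(parts, `[`, character(1), 2)),
    fraction = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE
  )
  new_expr_table(E, samples)
}

#' Full preprocessing of raw intensities to a normalized expression table
#'
#' MA transform, within-array loess colour normalization, dye-swap
#' combination, then between-array quantile normalization of the
#' combined log-ratio matrix (in that order).
#'
#' @param raw An `intensity_matrix`.
#' @param span Loess span.
#' @param quantile One of `"log_ratio"` (default: quantile-normalize
#'   the combined per-sample log2 ratios) or `"none"`.
#' @return An `expr_table`.
#' @export
normalize_arrays <- function(raw, span = 0.3,
                             quantile = c("log_ratio", "none")) {
  quantile <- match.arg(quantile)
  ma <- loess_normalize(compute_ma(raw), span = span)
  expr <- combine_dye_swaps(ma)
  if (quantile == "log_ratio") expr <- quantile_normalize(expr)
  expr
}

#' PCA quality control of replicates
#'
#' Centered PCA of the samples (genes are variables). Reports component
#' scores, variance-explained fractions (summing to 1), and a replicate
#' clustering summary: mean within-condition vs between-condition
#' distance of the sample scores.
#'
#' @param x An `expr_table` or a numeric matrix (genes x samples).
#' @param conditions Optional condition labels per sample (taken from
#'   the `expr_table` metadata if present).
#' @param n_components Number of components to retain in the scores.
#' @return List of class `pca_qc`: `scores`, `var_explained`,
#'   `within_distance`, `between_distance`.
#' @export
pca_qc <- function(x, conditions = NULL, n_components = 3) {
  if (inherits(x, "expr_table")) {
    if (is.null(conditions)) conditions <- x$samples$condition
    x <- x$E
  }
  if (ncol(x) < 2) stop("PCA QC needs >= 2 samples", call. = FALSE)
  if (all(apply(x, 1, sd) == 0)) {
    stop("constant matrix: no variance to decompose", call. = FALSE)
  }
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  within <- between <- NA_real_
  if (!is.null(conditions)) {
    d <- as.matrix(dist(scores))
    same <- outer(conditions, conditions, `==`)
    diag(same) <- NA
    within <- mean(d[which(same)], na.rm = TRUE)
    between <- mean(d[which(!same)], na.rm = TRUE)
  }
  structure(list(scores = scores, var_explained = ve,
                 within_distance = within, between_distance = between),
            class = "pca_qc")
}

#' @export
print.expr_table <- function(x, ...) {
  cat("Expression table:", nrow(x$E), "genes x", ncol(x$E),
      "samples\n")
  cat("  conditions:",
      paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("  fractions: ",
      paste(unique(x$samples$fraction), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pca_qc <- function(x, ...) {
  cat("PCA QC: variance explained",
      paste(sprintf("%.1f%%", 100 * head(x$var_explained, 3)),
            collapse = ", "), "(PC1-3)\n")
  if (!is.na(x$within_distance)) {
    cat(sprintf("  replicate distances: within %.3g, between %.3g\n",
                x$within_distance, x$between_distance))
  }
  invisible(x)
}
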