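# Moderated differential expression vs the excess-glucose control:
# per-gene contrasts on the normalized log2 ratios, empirical-Bayes
# variance shrinkage, BH FDR control and the +/-50% fold-change call
# rule.

# Newton inversion of the trigamma function (decreasing, convex on
# (0, Inf)); used by the method-of-moments fit of the variance prior.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

# Method-of-moments fit of a scaled inverse-chi-square prior to
# gene-wise variances s2 on df degrees of freedom, via the moments of
# log(s2): E log s2 = log s0^2 + digamma(df/2) - log(df/2)
#                    - digamma(d0/2) + log(d0/2),
# Var log s2 = trigamma(df/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  v <- var(e) - trigamma(df / 2)
  if (!is.finite(v) || v <= 0) {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(v)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Empirical-Bayes shrunken variances and moderated degrees of freedom.
moderate_variances <- function(s2, df) {
  prior <- fit_variance_prior(s2, df)
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_2, length(s2))
  } else {
    (prior$d0 * prior$s0_2 + df * s2) / (prior$d0 + df)
  }
  list(s2_post = s2_post, df_total = df + prior$d0, prior = prior)
}

# Shared two-group moderated-t engine: rows of `mat` are genes, columns
# split into condition and control groups.
moderated_two_group <- function(mat_c, mat_0, moderation = TRUE) {
  n1 <- ncol(mat_c); n0 <- ncol(mat_0)
  if (n1 < 2 || n0 < 2) {
    stop("at least 2 replicates per group required", call. = FALSE)
  }
  delta <- rowMeans(mat_c) - rowMeans(mat_0)
  df <- n1 + n0 - 2
  ss <- rowSums((mat_c - rowMeans(mat_c))^2) +
    rowSums((mat_0 - rowMeans(mat_0))^2)
  s2 <- ss / df
  if (moderation) {
    mod <- moderate_variances(s2, df)
    s2_use <- mod$s2_post
    df_use <- mod$df_total
  } else {
    s2_use <- s2
    df_use <- df
  }
  se <- sqrt(s2_use * (1 / n1 + 1 / n0))
  tt <- delta / se
  p <- 2 * pt(-abs(tt), df_use)
  # zero-variance genes with zero difference are nulls, not signals
  p[!is.finite(tt)] <- 1
  tt[!is.finite(tt)] <- 0
  list(log2fc = delta, t = tt, p = pmin(pmax(p, .Machine$double.xmin), 1),
       df = df_use, s2 = s2)
}

#' Per-gene condition contrasts against the control
#'
#' For every non-control condition, the per-gene log2 fold change is
#' the mean normalized log2 ratio in that condition minus the mean in
#' the control, tested with a two-sided moderated t-statistic. The
#' gene-wise variances are shrunk toward a pooled scaled
#' inverse-chi-square prior fitted by method of moments (empirical
#' Bayes); with `moderation = FALSE` an ordinary two-sample t on the
#' pooled variance is used. p-values are BH-adjusted within each
#' contrast.
#'
#' @param expr An `expr_table`; only columns of `fraction` are used if
#'   fraction metadata is present.
#' @param control Control condition id (e.g. `"D"`, excess glucose).
#' @param moderation Use empirical-Bayes variance shrinkage.
#' @param fraction Which RNA fraction to contrast (default `"total"`
#'   when present).
#' @return data.frame of class `contrast_table`: `gene_id`, `contrast`
#'   (e.g. "G-D"), `log2fc`, `t_statistic`, `p_value`, `adj_p`, `call`
#'   (all "ns" until [call_regulated()] is applied — it is applied with
#'   defaults here).
#' @export
fit_condition_contrasts <- function(expr, control, moderation = TRUE,
                                    fraction = "total") {
  samp <- expr$samples
  if (!is.null(samp$fraction) && fraction %in% samp$fraction) {
    keep <- samp$fraction == fraction
    samp <- samp[keep, ]
    E <- expr$E[, keep, drop = FALSE]
  } else {
    E <- expr$E
  }
  if (!control %in% samp$condition) {
    stop("unknown control condition: ", control, call. = FALSE)
  }
  conds <- setdiff(unique(samp$condition), control)
  mat_0 <- E[, samp$condition == control, drop = FALSE]
  out <- do.call(rbind, lapply(conds, function(cc) {
    mat_c <- E[, samp$condition == cc, drop = FALSE]
    fit <- moderated_two_group(mat_c, mat_0, moderation)
    data.frame(
      gene_id = rownames(E),
      contrast = paste0(cc, "-", control),
      log2fc = fit$log2fc,
      t_statistic = fit$t,
      p_value = fit$p,
      adj_p = bh_adjust(fit$p),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out <- call_regulated(out)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order
#' preserving. Input values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, elementwise >= the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Apply the fold-change / FDR regulation call rule
#'
#' A gene is called up in a contrast iff log2FC >= log2(fc) and
#' adjusted p < alpha; down iff log2FC <= -log2(fc) and adjusted
#' p < alpha; otherwise ns. The +/-50% fold-change cutoff is
#' interpreted log-symmetrically: |log2FC| >= log2(1.5) ~ 0.585.
#'
#' @param table A `contrast_table` (or any data.frame with `log2fc`
#'   and `adj_p`).
#' @param fc Linear fold-change cutoff (> 1).
#' @param alpha Adjusted-p cutoff.
#' @return The table with the `call` column set.
#' @export
call_regulated <- function(table, fc = 1.5, alpha = 0.05) {
  if (fc <= 1) stop("'fc' must be > 1", call. = FALSE)
  thr <- log2(fc)
  table$call <- ifelse(
    table$adj_p < alpha & table$log2fc >= thr, "up",
    ifelse(table$adj_p < alpha & table$log2fc <= -thr, "down", "ns")
  )
  table
}

#' Disjoint region counts of three gene sets (Venn partition)
#'
#' @param sets Named list of three character vectors over a common gene
#'   universe.
#' @return Named integer vector of the 7 disjoint region counts; the
#'   names combine set names with "&". Counts sum to the union size.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), 0, 3, dimnames = list(NULL, nm))
  }
  pattern <- apply(member, 1, function(r) {
    paste(nm[r], collapse = "&")
  })
  regions <- c(nm, paste(nm[c(1, 1, 2)], nm[c(2, 3, 3)], sep = "&"),
               paste(nm, collapse = "&"))
  counts <- setNames(integer(length(regions)), regions)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Regulated gene sets per contrast and direction
#'
#' @param table A `contrast_table` with calls.
#' @param direction `"up"` or `"down"`.
#' @return Named list of gene-id vectors, one per contrast.
#' @export
regulated_sets <- function(table, direction = c("up", "down")) {
  direction <- match.arg(direction)
  keep <- table$call == direction
  split(table$gene_id[keep],
        factor(table$contrast[keep], levels = unique(table$contrast)))
}
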