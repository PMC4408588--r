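make_tiny_intensities <- function(red, green, orientation) {
  genes <- sprintf("g%03d", seq_len(nrow(red)))
  arrays <- sprintf("A%02d", seq_len(ncol(red)))
  dimnames(red) <- dimnames(green) <- list(genes, arrays)
  sheet <- data.frame(
    array_id = arrays, condition = "D",
    replicate = rep(seq_len(ncol(red) / 2), each = 2)[seq_len(ncol(red))],
    fraction = "total", dye_orientation = orientation,
    stringsAsFactors = FALSE
  )
  class(sheet) <- c("sample_sheet", "data.frame")
  structure(list(red = red, green = green, genes = genes,
                 sheet = sheet), class = "intensity_matrix")
}

test_that("MA transform is orientation-corrected and rejects bad input", {
  red <- matrix(c(4, 1), 1, 2)
  green <- matrix(c(1, 4), 1, 2)
  im <- make_tiny_intensities(red, green,
                              c("sample_red", "sample_green"))
  ma <- compute_ma(im)
  # sample = 4, ref = 1 on both arrays after orientation correction
  expect_equal(unname(ma$M[1, ]), c(2, 2))
  expect_equal(unname(ma$A[1, ]), c(1, 1))

  im$red[1, 1] <- 0
  expect_error(compute_ma(im), "non-positive")
})

test_that("loess colour normalization removes the injected dye trend", {
  exp0 <- fx_null_experiment()
  ma <- compute_ma(exp0$arrays)
  pre <- ma_trend_magnitude(ma)
  # injected quadratic bias is visible before normalization...
  expect_gt(max(pre), 0.15 / 2)
  post <- ma_trend_magnitude(loess_normalize(ma))
  # ...and gone after
  expect_lt(max(post), 0.05)
})

test_that("bias-free arrays with sample = reference are left unchanged", {
  # one condition, one fraction, no noise: every sample equals the
  # pooled reference, so M = 0 and loess has nothing to remove
  catalog <- generate_gene_catalog(300, seed = 33)
  design <- data.frame(condition = "D", control = TRUE)
  tr <- generate_ground_truth(
    catalog, design,
    effects = effect_params(de_fraction = 0, ts_fraction = 0,
                            pm_ratio = c(D = 1)),
    seed = 33)
  ab <- simulate_fraction_abundances(tr, catalog, n_replicates = 2,
                                     noise_sd = 0, seed = 33)
  ab$abundance <- ab$abundance[, ab$samples$fraction == "total"]
  ab$samples <- ab$samples[ab$samples$fraction == "total", ]
  sheet <- make_sample_sheet(design, n_replicates = 2,
                             fractions = "total")
  arr <- simulate_arrays(ab, sheet,
                         bias_params(scale_sd = 0, dye_coef = c(0, 0, 0),
                                     noise_sd = 0), seed = 33)
  ma <- compute_ma(arr)
  man <- loess_normalize(ma)
  expect_lt(max(abs(man$M - ma$M)), 0.05)
  # and a constant offset in M is absorbed
  ma_off <- ma; ma_off$M <- ma$M + 0.8
  man_off <- loess_normalize(ma_off)
  expect_lt(max(abs(apply(man_off$M, 2, median))), 0.05)
})

test_that("quantile normalization maps columns to the mean distribution", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn[, "a"]), c(1.5, 3, 4.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 3, 4.5))

  # identical columns unchanged; sorted columns identical afterwards
  y <- matrix(rnorm(300), 100, 3)
  y_same <- cbind(y[, 1], y[, 1], y[, 1])
  expect_equal(quantile_normalize(y_same), y_same, ignore_attr = TRUE)
  qy <- quantile_normalize(y)
  sorted <- apply(qy, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2])
  expect_equal(sorted[, 2], sorted[, 3])
  # original within-column order preserved
  expect_equal(order(qy[, 1]), order(y[, 1]))

  # idempotent
  expect_equal(quantile_normalize(qy), qy, tolerance = 1e-12)

  expect_warning(one <- quantile_normalize(y[, 1, drop = FALSE]),
                 "no-op")
  expect_equal(one, y[, 1, drop = FALSE])
  y[1, 1] <- NA
  expect_error(quantile_normalize(y), "missing")
})

test_that("dye-swap combination averages orientations and halves noise", {
  # raw log ratios +1.2 (sample in red) and -0.8 (sample in green)
  # orientation-correct to +1.2 and +0.8; the combined value is +1.0
  red <- matrix(2^c(1.2, -0.8), 1, 2)
  green <- matrix(1, 1, 2)
  im <- make_tiny_intensities(red, green,
                              c("sample_red", "sample_green"))
  im$sheet$replicate <- c(1, 1)
  expr <- combine_dye_swaps(compute_ma(im))
  expect_equal(unname(expr$E[1, 1]), 1.0)

  # unpaired sample in strict mode
  im2 <- make_tiny_intensities(matrix(c(2, 2), 1, 2),
                               matrix(1, 1, 2),
                               c("sample_red", "sample_red"))
  im2$sheet$replicate <- c(1, 2)
  im2$sheet$fraction <- "total"
  ma2 <- compute_ma(im2)
  ma2$sheet$replicate <- c(1, 1)
  ma2$sheet$dye_orientation <- c("sample_red", "sample_red")
  expect_silent(combine_dye_swaps(ma2))  # two arrays, same key: paired

  ma2$sheet$replicate <- c(1, 2)
  expect_error(combine_dye_swaps(ma2), "unpaired.*D.2.total")

  # variance halving on null pairs: arrays whose sample equals the
  # reference pool, so every M is pure technical noise
  catalog <- generate_gene_catalog(1200, seed = 44)
  design <- data.frame(condition = "D", control = TRUE)
  tr <- generate_ground_truth(
    catalog, design,
    effects = effect_params(de_fraction = 0, ts_fraction = 0,
                            pm_ratio = c(D = 1)),
    seed = 44)
  ab <- simulate_fraction_abundances(tr, catalog, n_replicates = 3,
                                     noise_sd = 0, seed = 44)
  keep <- ab$samples$fraction == "total"
  ab$abundance <- ab$abundance[, keep]
  ab$samples <- ab$samples[keep, ]
  sheet <- make_sample_sheet(design, n_replicates = 3,
                             fractions = "total")
  arr <- simulate_arrays(ab, sheet,
                         bias_params(scale_sd = 0, dye_coef = c(0, 0, 0),
                                     noise_sd = 0.1), seed = 44)
  ma_null <- compute_ma(arr)
  expr_null <- combine_dye_swaps(ma_null)
  v_ratio <- mean(apply(expr_null$E, 2, var)) /
    mean(apply(ma_null$M, 2, var))
  expect_gt(v_ratio, 0.4)
  expect_lt(v_ratio, 0.6)
})

test_that("PCA QC matches a dense eigendecomposition oracle", {
  set.seed(71)
  x <- matrix(rnorm(12), 4, 3)
  qc <- pca_qc(x)
  # brute-force covariance eigenvalues of the centered sample matrix
  centered <- sweep(t(x), 2, colMeans(t(x)))
  ev <- eigen(stats::cov(centered))$values
  frac <- ev / sum(ev)
  k <- length(qc$var_explained)
  expect_equal(qc$var_explained, frac[seq_len(k)], tolerance = 1e-9)
  expect_equal(sum(qc$var_explained), 1, tolerance = 1e-9)

  # rank-1 data: PC1 explains everything
  r1 <- outer(rnorm(10), c(1, 2, 3))
  qc1 <- pca_qc(r1)
  expect_equal(qc1$var_explained[1], 1, tolerance = 1e-9)

  expect_error(pca_qc(matrix(1, 5, 3)), "constant")
  # replicates of the same condition cluster in score space
  eff <- fx_effect_experiment()
  tot <- eff$expr$samples$fraction == "total"
  sub <- structure(list(E = eff$expr$E[, tot],
                        samples = eff$expr$samples[tot, ]),
                   class = "expr_table")
  qc2 <- pca_qc(sub)
  expect_lt(qc2$within_distance, qc2$between_distance)
})

test_that("normalization order matters: loess before quantile", {
  exp0 <- fx_null_experiment()
  with_loess <- normalize_arrays(exp0$arrays)
  without_loess <- quantile_normalize(
    combine_dye_swaps(compute_ma(exp0$arrays)))
  trend_of <- function(expr) {
    ma <- compute_ma(exp0$arrays)
    # residual dye trend of the combined values vs average intensity
    a_mean <- sapply(unique(paste(exp0$sheet$condition,
                                  exp0$sheet$replicate,
                                  exp0$sheet$fraction, sep = ".")),
                     function(k) {
      cols <- which(paste(exp0$sheet$condition, exp0$sheet$replicate,
                          exp0$sheet$fraction, sep = ".") == k)
      rowMeans(ma$A[, cols, drop = FALSE])
    })
    mean(vapply(seq_len(ncol(expr$E)), function(j) {
      fit <- stats::lowess(a_mean[, colnames(expr$E)[j]], expr$E[, j],
                           f = 0.3, iter = 3)
      diff(range(fit$y))
    }, numeric(1)))
  }
  expect_lt(trend_of(with_loess), trend_of(without_loess))
})
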