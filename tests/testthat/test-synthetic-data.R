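test_that("gene catalog reproduces the annotated length distribution", {
  cat5k <- generate_gene_catalog(5000, seed = 7)
  expect_gt(mean(cat5k$orf_length), 1300)
  expect_lt(mean(cat5k$orf_length), 1600)
  expect_gt(median(cat5k$orf_length), 1100)
  expect_lt(median(cat5k$orf_length), 1300)
  expect_true(all(cat5k$orf_length >= 141 & cat5k$orf_length <= 14853))
  expect_true(all(cat5k$orf_length %% 3 == 0))
  expect_true(all(nchar(cat5k$cds) == cat5k$orf_length))
  expect_true(all(cat5k$baseline_abundance > 0))

  g <- assign_length_groups(cat5k$orf_length)
  utr_frac <- tapply(cat5k$utr5_length > 0, g, mean)
  expect_gt(utr_frac[["long"]], 0.45)
  expect_lt(utr_frac[["long"]], 0.55)
  expect_lt(utr_frac[["short"]], 0.06)

  scuo_means <- tapply(cat5k$scuo_true, g, mean)
  expect_equal(unname(scuo_means[["long"]]), 0.078, tolerance = 0.1)
  expect_equal(unname(scuo_means[["medium"]]), 0.105, tolerance = 0.1)
  expect_equal(unname(scuo_means[["short"]]), 0.198, tolerance = 0.1)
  # codon bias increases as length decreases
  expect_true(scuo_means[["short"]] > scuo_means[["medium"]])
  expect_true(scuo_means[["medium"]] > scuo_means[["long"]])
})

test_that("catalog generation is deterministic and validates input", {
  a <- generate_gene_catalog(50, seed = 9)
  b <- generate_gene_catalog(50, seed = 9)
  expect_identical(a, b)
  c2 <- generate_gene_catalog(50, seed = 10)
  expect_false(identical(a, c2))
  expect_error(generate_gene_catalog(5), ">= 12")
  expect_error(catalog_params(utr_prob = c(long = 1.5, medium = 0.1,
                                           short = 0)), "utr_prob")
})

test_that("ground truth honours the null design and the control", {
  catalog <- fx_catalog()
  t0 <- generate_ground_truth(
    catalog, effects = effect_params(de_fraction = 0, ts_fraction = 0),
    seed = 1)
  expect_true(all(t0$log2fc == 0))
  expect_true(all(t0$ts == 1))
  t1 <- generate_ground_truth(catalog, seed = 1)
  expect_true(all(t1$log2fc[, "D"] == 0))
  expect_true(all(t1$ts[, "D"] == 1))
  bad <- default_design(); bad$control <- c(TRUE, TRUE, FALSE, FALSE)
  expect_error(generate_ground_truth(catalog, design = bad),
               "exactly one control")
})

test_that("spiked effect counts match the configured fractions", {
  catalog <- generate_gene_catalog(2000, seed = 11)
  eff <- effect_params(de_fraction = 0.2, ts_fraction = 0.1)
  tr <- generate_ground_truth(catalog, effects = eff, seed = 11)
  for (cc in c("G", "M", "X")) {
    expect_equal(sum(tr$log2fc[, cc] != 0), round(0.2 * 2000))
    expect_equal(sum(tr$ts[, cc] != 1), round(0.1 * 2000))
  }
  # spiked magnitudes respect the stated mixture
  mag <- abs(tr$log2fc[tr$log2fc != 0])
  expect_true(all(mag >= 0.6 & mag <= 3))
  ts_eff <- tr$ts[tr$ts != 1]
  expect_true(all(ts_eff >= 1.5 | ts_eff <= 1 / 1.5))
  expect_error(effect_params(de_fraction = 1.4), "fractions")
})

test_that("pool mixing conserves total = monosome + polysome exactly", {
  exp0 <- fx_null_experiment()
  ab <- exp0$abund$abundance
  samp <- exp0$abund$samples
  for (cc in c("D", "X")) {
    for (r in 1:3) {
      tot <- ab[, paste(cc, r, "total", sep = ".")]
      mono <- ab[, paste(cc, r, "monosome", sep = ".")]
      poly <- ab[, paste(cc, r, "polysome", sep = ".")]
      expect_equal(tot, mono + poly, tolerance = 1e-12)
      expect_true(all(mono > 0) && all(poly > 0))
    }
  }
  # integrity regression on the simulator's own output is exact
  fi <- fraction_integrity(exp0$abund, "X")
  expect_equal(fi$r_squared, 1, tolerance = 1e-9)
  expect_equal(fi$slope, 1, tolerance = 1e-9)
})

test_that("noise-free symmetric mixing splits the pool in half", {
  catalog <- generate_gene_catalog(30, seed = 3,
    params = catalog_params(ts_length_slope = 0, ts_affinity_sd = 0))
  design <- data.frame(condition = "D", control = TRUE)
  tr <- generate_ground_truth(
    catalog, design,
    effects = effect_params(de_fraction = 0, ts_fraction = 0,
                            pm_ratio = c(D = 1)),
    seed = 3)
  ab <- simulate_fraction_abundances(tr, catalog, n_replicates = 1,
                                     noise_sd = 0, seed = 3)
  tot <- ab$abundance[, "D.1.total"]
  expect_equal(ab$abundance[, "D.1.polysome"], tot / 2,
               tolerance = 1e-12)
  expect_equal(ab$abundance[, "D.1.monosome"], tot / 2,
               tolerance = 1e-12)
})

test_that("arrays encode the sample/reference ratio when bias-free", {
  exp0 <- fx_null_experiment()
  arr0 <- simulate_arrays(
    exp0$abund, exp0$sheet,
    bias_params(scale_sd = 0, dye_coef = c(0, 0, 0), noise_sd = 0),
    seed = 5)
  ref <- rowMeans(exp0$abund$abundance)
  key <- paste(exp0$sheet$condition, exp0$sheet$replicate,
               exp0$sheet$fraction, sep = ".")
  for (i in c(1, 2, 40)) {
    truth_m <- log2(exp0$abund$abundance[, key[i]] / ref)
    raw_lr <- log2(arr0$red[, i] / arr0$green[, i])
    sgn <- if (exp0$sheet$dye_orientation[i] == "sample_red") 1 else -1
    expect_equal(sgn * raw_lr, truth_m, tolerance = 1e-10)
  }
  expect_true(all(arr0$red > 0) && all(arr0$green > 0))
  # determinism
  a1 <- simulate_arrays(exp0$abund, exp0$sheet, seed = 6)
  a2 <- simulate_arrays(exp0$abund, exp0$sheet, seed = 6)
  expect_identical(a1, a2)
})

test_that("sample sheet pairs every sample in both dye orientations", {
  sheet <- make_sample_sheet()
  expect_equal(nrow(sheet), 4 * 3 * 3 * 2)
  expect_false(any(duplicated(sheet$array_id)))
  key <- paste(sheet$condition, sheet$replicate, sheet$fraction)
  expect_true(all(table(key) == 2))
  per_key_orients <- tapply(sheet$dye_orientation, key,
                            function(x) length(unique(x)))
  expect_true(all(per_key_orients == 2))
})

test_that("simulated traces carry exact truth areas and are reproducible", {
  sim <- simulate_profile_trace(2.5, seed = 21)
  expect_equal(sim$truth$areas[["polysome"]] /
                 sim$truth$areas[["monosome"]], 2.5, tolerance = 1e-12)
  sim2 <- simulate_profile_trace(2.5, seed = 21)
  expect_identical(sim, sim2)
  expect_error(simulate_profile_trace(-1), "pm_ratio")
  expect_error(trace_params(n_poly = 2), "at least 3")
})
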