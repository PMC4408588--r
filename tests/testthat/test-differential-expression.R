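test_that("null data give uniform p-values and controlled FDR", {
  set.seed(81)
  E <- matrix(rnorm(5000 * 6, sd = 0.4), 5000, 6)
  expr <- fx_expr_table(E, condition = rep(c("D", "X"), each = 3),
                        replicate = rep(1:3, 2))
  de <- fit_condition_contrasts(expr, "D")
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  # FDR control over repeated null simulations (no fold-change filter)
  set.seed(82)
  rates <- replicate(50, {
    E <- matrix(rnorm(2000 * 6, sd = 0.4), 2000, 6)
    expr <- fx_expr_table(E, condition = rep(c("D", "X"), each = 3),
                          replicate = rep(1:3, 2))
    de <- fit_condition_contrasts(expr, "D")
    mean(de$adj_p < 0.05)
  })
  expect_lte(mean(rates), 0.10)
})

test_that("known fold changes are recovered", {
  set.seed(83)
  E <- matrix(rnorm(500 * 6, sd = 0.1), 500, 6)
  E[1:50, 4:6] <- E[1:50, 4:6] + 2
  expr <- fx_expr_table(E, condition = rep(c("D", "X"), each = 3),
                        replicate = rep(1:3, 2))
  de <- fit_condition_contrasts(expr, "D")
  expect_true(all(abs(de$log2fc[1:50] - 2) < 0.3))
  expect_true(all(de$call[1:50] == "up"))

  # identical condition and control columns -> exactly zero
  E2 <- matrix(rnorm(100 * 3), 100, 3)
  expr2 <- fx_expr_table(cbind(E2, E2),
                         condition = rep(c("D", "X"), each = 3),
                         replicate = rep(1:3, 2))
  de2 <- fit_condition_contrasts(expr2, "D")
  expect_true(all(de2$log2fc == 0))

  expect_error(fit_condition_contrasts(expr, "Q"), "unknown control")
})

test_that("moderated statistics track limma's empirical Bayes fit", {
  set.seed(84)
  n <- 400
  s <- sqrt(1 / rgamma(n, shape = 3, rate = 3))  # heterogeneous variances
  E <- matrix(rnorm(n * 6), n, 6) * s
  E[1:20, 4:6] <- E[1:20, 4:6] + 1.5
  expr <- fx_expr_table(E, condition = rep(c("D", "X"), each = 3),
                        replicate = rep(1:3, 2))
  de <- fit_condition_contrasts(expr, "D")
  fit <- limma::eBayes(limma::lmFit(E, cbind(1, rep(0:1, each = 3))))
  expect_equal(de$log2fc, unname(fit$coefficients[, 2]),
               tolerance = 1e-10)
  expect_gt(cor(de$t_statistic, fit$t[, 2]), 0.999)
  expect_lt(max(abs(de$t_statistic - fit$t[, 2]) /
                  pmax(abs(fit$t[, 2]), 1)), 0.05)
  # moderated and ordinary t agree in the large-replicate limit
  set.seed(85)
  E20 <- matrix(rnorm(200 * 40), 200, 40) * rep(s[1:200], 40)
  expr20 <- fx_expr_table(E20, condition = rep(c("D", "X"), each = 20),
                          replicate = rep(1:20, 2))
  de_mod <- fit_condition_contrasts(expr20, "D", moderation = TRUE)
  de_ord <- fit_condition_contrasts(expr20, "D", moderation = FALSE)
  expect_gt(cor(de_mod$t_statistic, de_ord$t_statistic), 0.99)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  set.seed(86)
  p <- runif(200)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("regulation calls apply the fold-change and FDR cutoffs", {
  tab <- data.frame(
    gene_id = c("AOX1", "b", "c", "d"),
    log2fc = c(7.00, 0.58, -2.0, -0.70),
    adj_p = c(0.001, 0.001, 0.20, 0.01)
  )
  out <- call_regulated(tab)
  # a strongly induced gene passes; 2^0.58 = 1.49 just misses +/-50%;
  # a large fold change with poor FDR stays ns
  expect_equal(out$call, c("up", "ns", "ns", "down"))
  expect_error(call_regulated(tab, fc = 1), "> 1")
})

test_that("negating the data swaps up and down calls exactly", {
  eff <- fx_effect_experiment()
  de <- fit_condition_contrasts(eff$expr, "D")
  neg <- eff$expr
  neg$E <- -neg$E
  de_neg <- fit_condition_contrasts(neg, "D")
  expect_equal(de$call == "up", de_neg$call == "down")
  expect_equal(de$call == "down", de_neg$call == "up")
})

test_that("venn partition counts match brute-force enumeration", {
  disjoint <- list(G = "a", M = "b", X = "c")
  vp <- venn_partition(disjoint)
  expect_equal(sum(vp), 3)
  expect_true(all(vp[grepl("&", names(vp))] == 0))

  same <- list(G = letters[1:5], M = letters[1:5], X = letters[1:5])
  vp2 <- venn_partition(same)
  expect_equal(unname(vp2[["G&M&X"]]), 5L)
  expect_equal(sum(vp2), 5)

  set.seed(87)
  sets <- list(G = sample(letters, 8), M = sample(letters, 12),
               X = sample(letters, 5))
  vp3 <- venn_partition(sets)
  universe <- unique(unlist(sets))
  brute <- table(vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
          collapse = "&")
  }, character(1)))
  expect_equal(sum(vp3), length(universe))
  for (nm in names(brute)) {
    expect_equal(unname(vp3[[nm]]), unname(as.integer(brute[[nm]])))
  }
})
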