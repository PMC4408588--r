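test_that("SCUO hits its bounds on forced-usage sequences", {
  # every amino acid uses exactly one codon: maximal order
  expect_equal(compute_scuo(strrep("GGCGAAACC", 20)), 1)
  # perfectly uniform synonymous usage: zero order
  # Lys (AAA/AAG) and Asp (GAT/GAC), both balanced
  expect_equal(compute_scuo(strrep("AAAAAGGATGAC", 15)), 0)
  expect_error(compute_scuo("AAAA"), "divisible by 3")
  expect_error(compute_scuo("ATGTGGTAA"), "no degenerate")
  expect_error(compute_scuo("ANNAAG"), "ambiguous")
  expect_equal(compute_scuo("ANNAAAAAGGATGAC", ambiguity = "skip"),
               compute_scuo("AAAAAGGATGAC"))
})

test_that("SCUO matches a brute-force tally oracle on random CDS", {
  gc_tab <- Biostrings::GENETIC_CODE
  fam <- split(names(gc_tab), unname(gc_tab))
  fam[c("M", "W", "*")] <- NULL
  oracle <- function(codons) {
    aa <- gc_tab[codons]
    keep <- !aa %in% c("M", "W", "*")
    aa <- aa[keep]; codons <- codons[keep]
    val <- 0
    for (a in unique(aa)) {
      tb <- table(codons[aa == a])
      p <- as.numeric(tb) / sum(tb)
      h <- -sum(p * log(p))
      n <- length(fam[[a]])
      val <- val + sum(aa == a) / length(aa) * (log(n) - h) / log(n)
    }
    val
  }
  set.seed(100)
  for (i in 1:10) {
    codons <- sample(names(gc_tab), 60, replace = TRUE)
    s <- paste(codons, collapse = "")
    got <- tryCatch(compute_scuo(s), error = function(e) NA)
    if (!is.na(got)) {
      expect_equal(got, oracle(codons), tolerance = 1e-12)
      expect_gte(got, 0); expect_lte(got, 1)
    }
  }
})

test_that("SCUO is invariant under synonymous relabeling", {
  # swapping which codon carries which count within a family cannot
  # change an entropy-based order measure
  s1 <- strrep(paste0(strrep("AAA", 3), "AAG"), 10)  # Lys 30:10
  s2 <- strrep(paste0(strrep("AAG", 3), "AAA"), 10)  # Lys 10:30
  expect_equal(compute_scuo(s1), compute_scuo(s2), tolerance = 1e-12)
})

test_that("length groups follow the strict annotation cutoffs", {
  expect_equal(as.character(assign_length_groups(c(2412, 1206, 540))),
               c("long", "medium", "short"))
  # boundary values belong to the medium group
  expect_equal(as.character(assign_length_groups(c(770, 1807))),
               c("medium", "medium"))
  expect_error(assign_length_groups(c(100, -5)), "positive")
  # every gene gets exactly one label
  lens <- generate_gene_catalog(500, seed = 13)$orf_length
  g <- assign_length_groups(lens)
  expect_false(anyNA(g))
  expect_equal(length(g), 500)
  # quantile mode splits at the input quartiles
  gq <- assign_length_groups(lens, mode = "quantile")
  expect_equal(unname(table(gq)[["long"]]),
               sum(lens > quantile(lens, 0.75)))
})

test_that("group summaries add up and degenerate groupings work", {
  catalog <- fx_catalog()
  gs <- summarize_groups(catalog)
  expect_equal(sum(gs$n_genes[gs$group != "all"]), nrow(catalog))
  expect_equal(gs$n_genes[gs$group == "all"], nrow(catalog))

  # a single-level custom grouping reproduces whole-population stats
  one <- factor(rep("everything", nrow(catalog)))
  gs1 <- summarize_groups(catalog, groups = one)
  expect_equal(gs1$mean_orf_length[1],
               gs1$mean_orf_length[gs1$group == "all"])
  expect_equal(gs1$mean_scuo[1], gs1$mean_scuo[gs1$group == "all"])

  # an empty declared group is an error
  bad <- factor(rep("medium", nrow(catalog)),
                levels = c("long", "medium", "short"))
  expect_error(summarize_groups(catalog, groups = bad), "empty")
})

test_that("length-group pattern matches the annotated trends", {
  eff <- fx_effect_experiment()
  ts <- compute_translational_state(eff$expr)
  ei <- expression_intensity(eff$arrays)
  gs <- summarize_groups(eff$catalog, expr = ei, ts = ts)
  short <- gs[gs$group == "short", ]
  long <- gs[gs$group == "long", ]
  expect_gt(short$mean_expression, long$mean_expression)
  expect_gt(short$mean_scuo, long$mean_scuo)
  expect_gt(short$mean_translational_state,
            long$mean_translational_state)
  expect_lt(short$pct_utr5, long$pct_utr5)
})

test_that("association battery finds the built-in relationships", {
  eff <- fx_effect_experiment()
  ts <- compute_translational_state(eff$expr)
  ei <- expression_intensity(eff$arrays)
  at <- association_tests(eff$catalog, expr = ei, ts = ts)

  get <- function(nm) at[at$test == nm, ]
  # expression falls with length
  expr_row <- get("expression_vs_length_lm")
  expect_lt(expr_row$estimate, 0)
  expect_lt(expr_row$p_value, 0.01)
  # codon bias falls with length (negative rank correlation)
  sc_row <- get("scuo_vs_length_spearman")
  expect_lt(sc_row$estimate, 0)
  expect_lt(sc_row$p_value, 1e-6)
  # translational state falls with length
  ts_row <- get("ts_vs_length_lm")
  expect_lt(ts_row$estimate, 0)
  expect_lt(ts_row$p_value, 0.01)
  # 5'UTR presence is strongly associated with length group
  expect_lt(get("utr_vs_length_group_fisher")$p_value, 1e-6)
  expect_lt(get("utr_vs_length_group_chisq")$p_value, 1e-6)
  # Shapiro-Wilk and pairwise Wilcoxon rows are present
  expect_true(any(grepl("shapiro", at$test)))
  expect_true(all(c("scuo_wilcoxon_long_vs_short",
                    "scuo_wilcoxon_long_vs_medium",
                    "scuo_wilcoxon_medium_vs_short") %in% at$test))
  expect_lt(get("scuo_wilcoxon_long_vs_short")$p_value, 1e-6)

  expect_error(association_tests(eff$catalog[1:10, ]), ">= 20")
})
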