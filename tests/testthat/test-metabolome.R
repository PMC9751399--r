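test_that("fold changes are ratios of replicate means", {
  # identical conditions -> fc = 1 everywhere
  p1 <- make_toy_panel(effects = c())
  expect_true(all(fold_changes(p1)$fc == 1))

  # treated = 2 x control -> fc = 2
  p2 <- make_toy_panel(effects = c(a = 2, b = 2, c = 2))
  expect_true(all(fold_changes(p2)$fc == 2))

  # means by hand: control (1,2,3), treated (2,4,6) -> 4/2 = 2
  p3 <- tibble::tibble(
    cell_line = "cl1", metabolite = "m",
    condition = rep(c("control", "treated"), each = 3),
    replicate = rep(1:3, 2),
    concentration = c(1, 2, 3, 2, 4, 6)
  )
  expect_equal(fold_changes(p3)$fc, 2)

  # zero control mean names the offending entry
  p4 <- dplyr::mutate(p3, concentration = ifelse(condition == "control", 0,
                                                 concentration))
  expect_error(fold_changes(p4), "cl1/m",
               class = "metresist_undefined_fc_error")

  # missing condition is rejected
  p5 <- dplyr::filter(p3, condition == "control")
  expect_error(fold_changes(p5), class = "metresist_input_error")
})

test_that("signed-rank test against unity reproduces hand-enumerated cases", {
  # 13 fold changes all above 1: only the all-positive sign pattern is as
  # extreme, so p = 2 / 2^13
  res <- wilcoxon_vs_unity(seq(1.1, 2.3, length.out = 13))
  expect_equal(res$p_two_sided, 2 / 2^13)
  expect_equal(res$direction, "increased")

  # worked 5-value case: W- = 2, p = 6/32
  res2 <- wilcoxon_vs_unity(c(1.25, 1.5, 0.85, 1.1, 1.3))
  expect_equal(res2$w_statistic, 2)
  expect_equal(res2$p_two_sided, 6 / 32)

  # perfectly balanced ranks around 1 -> p = 1, unchanged
  res3 <- wilcoxon_vs_unity(c(1.2, 0.8, 1.3, 0.7, 1.1, 0.9))
  expect_equal(res3$p_two_sided, 1)
  expect_equal(res3$direction, "unchanged")

  expect_error(wilcoxon_vs_unity(c(1.1, 1.2, 1.3, 1)),
               class = "metresist_insufficient_data_error")
  expect_error(wilcoxon_vs_unity(c(-1, 1.2, 1.3, 1.4, 1.5)),
               class = "metresist_input_error")
})

test_that("exact signed-rank p matches brute-force enumeration, ties included", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    fc <- exp(rnorm(n, sd = 0.3))
    if (i %% 3 == 0) fc <- 1 + round(fc - 1, 1)  # force ties and zeros
    fc <- fc[fc > 0]
    if (sum(fc != 1) < 5) next
    expect_equal(wilcoxon_vs_unity(fc)$p_two_sided, oracle_signed_rank_p(fc),
                 tolerance = 1e-12)
  }
})

test_that("large-n normal approximation stays close to the exact tail", {
  set.seed(7)
  fc <- exp(rnorm(26, mean = 0.08, sd = 0.2))
  fc <- fc[fc != 1]
  approx_p <- wilcoxon_vs_unity(fc)$p_two_sided
  exact_p <- stats::wilcox.test(fc, mu = 1, exact = TRUE)$p.value
  expect_lt(abs(approx_p - exact_p), 0.01)
})

test_that("modulated metabolites are partitioned by direction", {
  # all unchanged
  res <- dplyr::bind_rows(
    wilcoxon_vs_unity(c(1.2, 0.8, 1.3, 0.7, 1.1, 0.9), metabolite = "x"),
    wilcoxon_vs_unity(c(1.1, 0.9, 1.2, 0.8, 1.05, 0.95), metabolite = "y")
  )
  cls <- classify_modulated(res)
  expect_equal(cls$increased, character(0))
  expect_equal(cls$decreased, character(0))

  # noise-free planted effects are recovered exactly
  panel <- make_toy_panel(
    cell_lines = paste0("cl", 1:13), metabolites = letters[1:10],
    effects = c(a = 2, b = 2, c = 0.5))
  # metabolites whose fold changes are all exactly 1 drop out with a warning
  expect_warning(scr <- metabolome_screen(panel), "usable fold changes")
  cls2 <- classify_modulated(scr)
  expect_equal(cls2$increased, c("a", "b"))
  expect_equal(cls2$decreased, "c")

  expect_error(classify_modulated(dplyr::bind_rows(res, res[1, ])),
               class = "metresist_input_error")
})

test_that("pearson_with_p matches the worked example and textbook formula", {
  res <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$p_two_sided, 0.2)

  # antisymmetry: reversing x flips r, keeps p
  res2 <- pearson_with_p(c(4, 3, 2, 1), c(1, 3, 2, 4))
  expect_equal(res2$r, -0.8)
  expect_equal(res2$p_two_sided, res$p_two_sided)

  # exact linear relation
  x <- c(1, 2, 5, 9)
  res3 <- pearson_with_p(x, 2 * x + 3)
  expect_equal(res3$r, 1)
  expect_gt(res3$p_two_sided, 0)

  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)),
               class = "metresist_undefined_correlation_error")
  expect_error(pearson_with_p(c(1, 2), c(1, 2)),
               class = "metresist_insufficient_data_error")
})

test_that("pearson_with_p is invariant under affine maps, up to the sign of r", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    base <- pearson_with_p(x, y)
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    tr <- pearson_with_p(a + b * x, y)
    expect_equal(tr$r, sign(b) * base$r, tolerance = 1e-12)
    expect_equal(tr$p_two_sided, base$p_two_sided, tolerance = 1e-12)
  }
})

test_that("the correlation screen recovers planted associations and tiers", {
  b <- simulate_panel(simulation_config(
    n_cell_lines = 200, n_metabolites = 6, n_genes = 20,
    resistance_corr_target = 0.7, seed = 9))
  scr <- correlation_screen(b$metabolite_panel, b$phenotypes)
  gsh_row <- dplyr::filter(scr, .data$feature == "glutathione",
                           .data$phenotype == "mtx_ic50_96_nM",
                           .data$condition == "control")
  expect_lt(abs(gsh_row$r - 0.7), 0.1)
  expect_equal(gsh_row$tier, "significant")
  # full rectangle: metabolites x phenotypes x conditions
  expect_equal(nrow(scr), 6 * 3 * 2)
})

test_that("a feature duplicated from a phenotype correlates perfectly", {
  ph <- tibble::tibble(cell_line = paste0("c", 1:5),
                       doubling_time_days = c(1, 1.5, 2, 2.5, 3),
                       mtx_ic50_48_nM = c(20, 30, 25, 40, 35),
                       mtx_ic50_96_nM = c(10, 12, 9, 20, 15))
  feat <- tibble::tibble(cell_line = ph$cell_line, metabolite = "copy",
                         fc = ph$mtx_ic50_96_nM)
  scr <- correlation_screen(feat, ph)
  row <- dplyr::filter(scr, .data$phenotype == "mtx_ic50_96_nM")
  expect_equal(row$r, 1)
  expect_equal(unique(scr$condition), "n/a")
  expect_error(correlation_screen(feat[1:2, ], ph),
               class = "metresist_insufficient_data_error")
})

test_that("a null panel keeps the significant fraction near the test level", {
  b <- simulate_panel(simulation_config(
    n_cell_lines = 30, n_metabolites = 40, n_genes = 20,
    effect_metabolites = c(met_001 = 1),   # no real effects
    resistance_corr_target = 0, prolif_corr_target = 0, seed = 21))
  scr <- correlation_screen(b$metabolite_panel, b$phenotypes)
  frac <- mean(scr$tier == "significant")
  expect_lt(frac, 0.12)
})

test_that("hypergeometric over-representation matches the closed form", {
  background <- c(paste0("hit", 1:31), paste0("null", 1:39))
  modulated <- paste0("hit", 1:31)
  sets <- list(
    full_hit = paste0("hit", 1:5),
    mixed = c(paste0("hit", 1:2), paste0("null", 1:3)),
    outside = paste0("zz", 1:4)
  )
  expect_warning(res <- msea_ora(modulated, background, sets), "outside")
  expect_equal(
    res$p_hypergeometric[res$set_name == "full_hit"],
    choose(31, 5) / choose(70, 5))
  expect_false("outside" %in% res$set_name)
  expect_true(all(diff(res$p_hypergeometric) >= 0))  # sorted by p
  expect_true(all(res$q_bh >= res$p_hypergeometric - 1e-15))

  expect_error(msea_ora(c("x"), background, sets),
               class = "metresist_input_error")
  expect_error(msea_ora(character(0), character(0), sets),
               class = "metresist_input_error")
})

test_that("ORA p-values decrease as the overlap grows at fixed set size", {
  background <- paste0("m", 1:70)
  modulated <- paste0("m", 1:31)
  ps <- vapply(0:5, function(k) {
    members <- c(paste0("m", seq_len(k)), paste0("m", 66 - seq_len(5 - k)))
    msea_ora(modulated, background, list(s = members))$p_hypergeometric
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})
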