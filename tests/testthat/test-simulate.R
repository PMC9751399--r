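test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_cell_lines = 1), "n_cell_lines",
               class = "metresist_config_error")
  expect_error(simulation_config(replicate_cv = -0.1), "replicate_cv",
               class = "metresist_config_error")
  expect_error(simulation_config(resistance_corr_target = 1),
               "resistance_corr_target", class = "metresist_config_error")
  expect_error(simulation_config(ic50_range_nM = c(10, 5)), "ic50_range_nM",
               class = "metresist_config_error")
  expect_error(
    simulation_config(effect_metabolites = c(glutathione = -2)),
    "effect_metabolites", class = "metresist_config_error")
  expect_error(
    simulate_panel(simulation_config(effect_metabolites = c(nonexistent = 2))),
    "unknown metabolites", class = "metresist_config_error")
})

test_that("equal seeds give identical bundles; different seeds differ", {
  cfg <- simulation_config(n_cell_lines = 8, n_metabolites = 12,
                           n_genes = 50, seed = 123)
  b1 <- simulate_panel(cfg)
  b2 <- simulate_panel(cfg)
  expect_identical(b1, b2)
  b3 <- simulate_panel(simulation_config(n_cell_lines = 8, n_metabolites = 12,
                                         n_genes = 50, seed = 124))
  expect_false(identical(b1$metabolite_panel, b3$metabolite_panel))
})

test_that("noise-free planted effects appear exactly in every fold change", {
  cfg <- simulation_config(n_cell_lines = 6, n_metabolites = 8, n_genes = 40,
                           replicate_cv = 0,
                           effect_metabolites = c(met_003 = 2.0), seed = 5)
  fc <- fold_changes(simulate_panel(cfg)$metabolite_panel)
  expect_equal(fc$fc[fc$metabolite == "met_003"], rep(2, 6))
  expect_equal(fc$fc[fc$metabolite != "met_003"],
               rep(1, sum(fc$metabolite != "met_003")))
})

test_that("the planted GSH-resistance correlation is recovered at large n", {
  rs <- vapply(1:20, function(s) {
    b <- simulate_panel(simulation_config(
      n_cell_lines = 200, n_metabolites = 5, n_genes = 20,
      resistance_corr_target = 0.7, seed = s))
    gsh <- b$metabolite_panel |>
      dplyr::filter(.data$metabolite == "glutathione",
                    .data$condition == "control") |>
      dplyr::group_by(.data$cell_line) |>
      dplyr::summarise(v = mean(.data$concentration), .groups = "drop")
    j <- dplyr::inner_join(gsh, b$phenotypes, by = "cell_line")
    cor(j$v, j$mtx_ic50_96_nM)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.7), 0.1)
})

test_that("the planted proliferation-early-resistance correlation is recovered", {
  rs <- vapply(1:10, function(s) {
    ph <- simulate_panel(simulation_config(
      n_cell_lines = 200, n_metabolites = 5, n_genes = 20,
      prolif_corr_target = 0.83, seed = 100 + s))$phenotypes
    cor(ph$doubling_time_days, ph$mtx_ic50_48_nM)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.83), 0.1)
})

test_that("simulated viability follows the Hill law exactly without noise", {
  s <- simulate_viability(10, hill_slope = 1, doses = c(1, 10, 30, 100),
                          times = 48, noise_cv = 0)
  expect_equal(s$live_fraction[s$dose == 10], 0.5)     # midpoint
  expect_equal(s$live_fraction[s$dose == 30], 0.25)    # 1/(1+3)
  lo <- simulate_viability(10, 1, doses = c(1e-6, 1e6), times = 48)
  expect_gt(lo$live_fraction[lo$dose == 1e-6], 0.999)  # c -> 0  => f -> 1
  expect_lt(lo$live_fraction[lo$dose == 1e6], 0.001)   # c -> Inf => f -> 0
})

test_that("a 48h/96h potency anchor pair decays geometrically in time", {
  s <- simulate_viability(c(20, 10), 1, doses = c(10, 20), times = c(48, 72, 96))
  # at 48 h the IC50 is 20; at 96 h it is 10; at 72 h geometric mean sqrt(200)
  expect_equal(s$live_fraction[s$dose == 20 & s$time_h == 48], 0.5)
  expect_equal(s$live_fraction[s$dose == 10 & s$time_h == 96], 0.5)
  f72 <- s$live_fraction[s$dose == 20 & s$time_h == 72]
  expect_equal(f72, 1 / (1 + 20 / sqrt(200)))
})

test_that("viability simulation rejects malformed grids", {
  expect_error(simulate_viability(10, 1, doses = numeric(0), times = 48),
               class = "metresist_input_error")
  expect_error(simulate_viability(10, 1, doses = c(10, 5), times = 48),
               class = "metresist_input_error")
  expect_error(simulate_viability(10, 1, doses = c(5, 10), times = c(96, 48)),
               class = "metresist_input_error")
  expect_error(simulate_viability(-1, 1, doses = c(5, 10), times = 48),
               class = "metresist_input_error")
})

test_that("simulated combinations carry the planted synergy offset", {
  doses <- 2^seq(-3, 5) * 10
  a <- simulate_viability(10, 1, doses, c(48, 96), drug = "A")
  b <- simulate_viability(20, 1, doses, c(48, 96), drug = "B")
  design <- combination_design("A", "B", ratio_rho = 1)

  # lambda = 0 reproduces the Bliss additive surface exactly
  c0 <- simulate_combination(a, b, ratio = 1, lambda = 0)
  add <- bliss_additive_surface(a, b, design, ray_doses = sort(unique(a$dose)))
  expect_equal(c0$live_fraction, add$live_fraction)

  # lambda = 1 halves the combination LD50 relative to additivity
  c1 <- suppressWarnings(simulate_combination(a, b, ratio = 1, lambda = 1))
  ld_add <- ld50_at_time(add, 96, method = "interp")$ic50
  ld_c1 <- ld50_at_time(c1, 96, method = "interp")$ic50
  expect_equal(ld_c1, ld_add / 2, tolerance = 1e-6)

  # mismatched time grids are an alignment error
  b_bad <- simulate_viability(20, 1, doses, c(24, 72), drug = "B")
  expect_error(simulate_combination(a, b_bad, ratio = 1, lambda = 0),
               class = "metresist_alignment_error")
})
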