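hill_surface <- function(ic50, doses, drug, h = 1, times = c(48, 96)) {
  simulate_viability(ic50, h, doses, times, drug = drug)
}

test_that("the Bliss additive surface is the product of surviving fractions", {
  doses <- c(1, 10, 100)
  # constant-fraction surfaces: f_a = 0.6, f_b = 0.5 -> additive 0.30
  f_a <- tibble::tibble(drug = "A", cell_line = "c", dose = doses,
                        time_h = 48, replicate = 1, live_fraction = 0.6)
  f_b <- dplyr::mutate(f_a, drug = "B", live_fraction = 0.5)
  design <- combination_design("A", "B", ratio_rho = 1)
  add <- bliss_additive_surface(f_a, f_b, design)
  expect_equal(add$live_fraction, rep(0.3, 3))

  # an inert partner leaves the active agent's surface unchanged
  a <- hill_surface(10, 10^seq(-1, 3, length.out = 9), "A")
  inert <- dplyr::mutate(a, drug = "B", live_fraction = 1)
  add2 <- bliss_additive_surface(a, inert, design)
  slice_a <- dplyr::filter(a, .data$time_h == 96)
  slice_add <- dplyr::filter(add2, .data$time_h == 96)
  expect_equal(slice_add$live_fraction, slice_a$live_fraction,
               tolerance = 1e-9)

  # two identical Hill curves (h = 1), rho = 1, total-dose reference:
  # at total dose 2*IC50 each component sits at its IC50 -> 0.5 * 0.5
  b <- dplyr::mutate(a, drug = "B")
  design_tot <- combination_design("A", "B", ratio_rho = 1,
                                   dose_reference = "total")
  add3 <- bliss_additive_surface(a, b, design_tot, ray_doses = 20)
  expect_equal(add3$live_fraction, rep(0.25, 2), tolerance = 1e-9)

  # mismatched time grids are an alignment error
  b_bad <- hill_surface(10, doses, "B", times = c(24, 72))
  expect_error(bliss_additive_surface(a, b_bad, design),
               class = "metresist_alignment_error")
})

test_that("the synergy score is zero on the additive surface and log2 of a shift", {
  doses <- 2^seq(-4, 6, by = 0.5) * 10
  a <- hill_surface(c(20, 10), doses, "A")
  b <- hill_surface(c(40, 20), doses, "B", h = 1.3)
  design <- combination_design("A", "B", ratio_rho = 1)

  combo0 <- simulate_combination(a, b, ratio = 1, lambda = 0)
  s0 <- synergy_score(a, b, combo0, design, t = 96, method = "interp")
  expect_equal(s0$score, 0, tolerance = 1e-9)
  expect_equal(s0$call, "additive")

  combo1 <- suppressWarnings(simulate_combination(a, b, ratio = 1, lambda = 1))
  s1 <- suppressWarnings(
    synergy_score(a, b, combo1, design, t = 96, method = "interp"))
  expect_equal(s1$score, 1, tolerance = 0.02)
  expect_equal(s1$call, "synergy")

  for (lam in c(-1, 0.5)) {
    combo <- suppressWarnings(
      simulate_combination(a, b, ratio = 1, lambda = lam))
    s <- suppressWarnings(
      synergy_score(a, b, combo, design, t = 96, method = "interp"))
    expect_equal(s$score, lam, tolerance = 0.02)
  }
})

test_that("the score is invariant to dose-unit rescaling", {
  doses <- 2^seq(-3, 5, by = 0.5) * 5
  a <- hill_surface(c(12, 6), doses, "A")
  b <- hill_surface(c(30, 18), doses, "B")
  design <- combination_design("A", "B", ratio_rho = 2)
  combo <- suppressWarnings(
    simulate_combination(a, b, ratio = 2, lambda = 0.5))
  s <- suppressWarnings(
    synergy_score(a, b, combo, design, t = 96, method = "interp"))
  k <- 1000
  scale_surface <- function(surf) dplyr::mutate(surf, dose = .data$dose * k)
  s_scaled <- suppressWarnings(synergy_score(
    scale_surface(a), scale_surface(b), scale_surface(combo),
    design, t = 96, method = "interp"))
  expect_equal(s_scaled$score, s$score, tolerance = 1e-9)
})

test_that("swapping drug labels with rho -> 1/rho leaves the score unchanged", {
  doses <- 2^seq(-4, 6, by = 0.25) * 10
  rho <- 3
  a <- hill_surface(c(20, 10), doses, "A")
  b <- hill_surface(c(60, 30), doses, "B", h = 1.2)
  design_ab <- combination_design("A", "B", ratio_rho = rho)
  combo <- suppressWarnings(
    simulate_combination(a, b, ratio = rho, lambda = 0.4))
  s_ab <- suppressWarnings(
    synergy_score(a, b, combo, design_ab, t = 96, method = "interp"))

  # same physical combination referenced to drug B's axis: c_b = rho * c_a
  design_ba <- combination_design("B", "A", ratio_rho = 1 / rho)
  combo_b <- dplyr::mutate(combo, dose = .data$dose * rho)
  s_ba <- suppressWarnings(
    synergy_score(b, a, combo_b, design_ba, t = 96, method = "interp"))
  expect_equal(s_ba$score, s_ab$score, tolerance = 1e-6)
})

test_that("a combination dominating the additive surface scores as antagonism", {
  doses <- 2^seq(-4, 6, by = 0.5) * 10
  a <- hill_surface(c(20, 10), doses, "A")
  b <- hill_surface(c(40, 20), doses, "B")
  design <- combination_design("A", "B", ratio_rho = 1)
  combo_antag <- suppressWarnings(
    simulate_combination(a, b, ratio = 1, lambda = -0.8))
  add <- bliss_additive_surface(a, b, design, ray_doses = sort(unique(a$dose)))
  # the lambda < 0 surface lies above the additive prediction pointwise
  expect_true(all(combo_antag$live_fraction >= add$live_fraction - 1e-12))
  s <- suppressWarnings(
    synergy_score(a, b, combo_antag, design, t = 96, method = "interp"))
  expect_lt(s$score, 0)
  expect_equal(s$call, "antagonism")
})

test_that("censored LD50s propagate to bounded, classifiable scores", {
  doses <- c(1, 3, 9, 27, 81)
  a <- hill_surface(10, doses, "A")
  b <- hill_surface(10, doses, "B")
  design <- combination_design("A", "B", ratio_rho = 1)
  # combination too weak to reach 50% kill within the tested range
  combo_weak <- dplyr::mutate(
    simulate_combination(a, b, ratio = 1, lambda = 0),
    live_fraction = pmin(1, .data$live_fraction + 0.6))
  s <- synergy_score(a, b, combo_weak, design, t = 96, method = "interp")
  expect_true(is.na(s$score))
  expect_match(s$censored, "combination_above_max")
  expect_equal(s$bound_type, "le")

  # classification from bounds alone
  stub <- tibble::tibble(score = NA_real_, bound_type = "ge", bound_value = 0.4)
  expect_equal(classify_interaction(stub)$call, "synergy")
  stub2 <- tibble::tibble(score = NA_real_, bound_type = "le",
                          bound_value = -0.6)
  expect_equal(classify_interaction(stub2)$call, "antagonism")
  stub3 <- tibble::tibble(score = NA_real_, bound_type = "le",
                          bound_value = 0.1)
  expect_true(is.na(classify_interaction(stub3)$call))

  # direct-score calls at the default threshold
  direct <- tibble::tibble(score = c(0, 1, -1), bound_type = "none",
                           bound_value = NA_real_)
  expect_equal(classify_interaction(direct)$call,
               c("additive", "synergy", "antagonism"))
  expect_error(classify_interaction(direct, threshold = -1),
               class = "metresist_input_error")
})
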