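#' Simulation configuration for a synthetic resistance-screen panel
#'
#' Builds and validates the configuration for [simulate_panel()]. The defaults
#' emulate the study design the pipeline targets: a 13-cell-line panel (6
#' B-cell precursor, 7 T-lineage) profiled for 70 metabolites in control and
#' drug-treated conditions with 3 biological replicates, drug potency (IC50)
#' measured at a 48 h and a 96 h horizon, and a log2 expression matrix with
#' gene sets.
#'
#' Planted structure, all recoverable by the downstream screens:
#' * a subset of metabolites carries a multiplicative treatment effect
#'   (default: 19 increased with multipliers 1.4--2.2, 12 decreased with
#'   multipliers 0.45--0.8);
#' * the designated glutathione-like metabolite's per-cell-line level is
#'   correlated with the late (96 h) IC50 at `resistance_corr_target`;
#' * doubling time is correlated with the early (48 h) IC50 at
#'   `prolif_corr_target` (slow-dividing lines resist an antiproliferative
#'   drug in the short term);
#' * the members of one gene set track the glutathione-like metabolite's
#'   latent level.
#'
#' @param n_cell_lines Number of cell lines (>= 2). Default 13.
#' @param n_metabolites Number of metabolites (>= 2). Default 70.
#' @param n_replicates Biological replicates per condition (>= 2). Default 3.
#' @param n_genes Number of genes in the expression matrix. Default 1000.
#' @param effect_metabolites Named numeric vector mapping metabolite name to a
#'   multiplicative treatment effect (> 0). `NULL` uses the default 19-up /
#'   12-down plan on generically named metabolites.
#' @param resistance_corr_target Pearson correlation planted between the
#'   glutathione-like metabolite's cell-line mean and the 96 h IC50, in
#'   (-1, 1). Default 0.7.
#' @param prolif_corr_target Pearson correlation planted between doubling time
#'   and the 48 h IC50, in (-1, 1). Default 0.83.
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise (>= 0). Default 0.1.
#' @param lambda Synergy offset on the log2 dose axis used by
#'   [simulate_combination()]; the true synergy score of a simulated
#'   combination equals `lambda`. Default 0.5.
#' @param hill_slope Hill slope of simulated dose-response curves (> 0).
#' @param ic50_range_nM Length-2 positive interval for the 96 h IC50 across
#'   cell lines (nM). Default `c(5.5, 38.4)`.
#' @param ic50_48_range_nM Length-2 positive interval for the 48 h IC50 (nM).
#'   Default `c(10.8, 101.1)`.
#' @param gene_set_corr Correlation between planted gene-set members'
#'   expression and the glutathione-like latent level. Default 0.7.
#' @param n_gene_sets Number of gene sets generated (one planted + background).
#' @param seed Integer seed; equal seeds give byte-identical bundles.
#'
#' @returns A validated list of class `"simulation_config"`.
#' @seealso [simulate_panel()]
#' @export
simulation_config <- function(n_cell_lines = 13,
                              n_metabolites = 70,
                              n_replicates = 3,
                              n_genes = 1000,
                              effect_metabolites = NULL,
                              resistance_corr_target = 0.7,
                              prolif_corr_target = 0.83,
                              replicate_cv = 0.1,
                              lambda = 0.5,
                              hill_slope = 1,
                              ic50_range_nM = c(5.5, 38.4),
                              ic50_48_range_nM = c(10.8, 101.1),
                              gene_set_corr = 0.7,
                              n_gene_sets = 20,
                              seed = 1L) {
  config <- list(
    n_cell_lines = n_cell_lines, n_metabolites = n_metabolites,
    n_replicates = n_replicates, n_genes = n_genes,
    effect_metabolites = effect_metabolites,
    resistance_corr_target = resistance_corr_target,
    prolif_corr_target = prolif_corr_target,
    replicate_cv = replicate_cv, lambda = lambda, hill_slope = hill_slope,
    ic50_range_nM = ic50_range_nM, ic50_48_range_nM = ic50_48_range_nM,
    gene_set_corr = gene_set_corr, n_gene_sets = n_gene_sets,
    seed = as.integer(seed)
  )

  bad <- function(field, why) {
    stop_input(sprintf("invalid simulation config: field '%s' %s", field, why),
               class = "metresist_config_error")
  }
  for (field in c("n_cell_lines", "n_metabolites", "n_replicates", "n_genes")) {
    v <- config[[field]]
    if (!is_scalar_number(v) || v < 2 || v != round(v)) {
      bad(field, "must be an integer count >= 2")
    }
  }
  if (!is_scalar_number(replicate_cv) || replicate_cv < 0) {
    bad("replicate_cv", "must be >= 0")
  }
  for (field in c("resistance_corr_target", "prolif_corr_target",
                  "gene_set_corr")) {
    v <- config[[field]]
    if (!is_scalar_number(v) || abs(v) >= 1) bad(field, "must lie in (-1, 1)")
  }
  if (!is_scalar_number(lambda)) bad("lambda", "must be a finite number")
  if (!is_scalar_number(hill_slope) || hill_slope <= 0) {
    bad("hill_slope", "must be > 0")
  }
  for (field in c("ic50_range_nM", "ic50_48_range_nM")) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 2 || any(v <= 0) || v[1] >= v[2]) {
      bad(field, "must be a positive increasing interval")
    }
  }
  if (!is.null(effect_metabolites)) {
    if (!is.numeric(effect_metabolites) || is.null(names(effect_metabolites)) ||
        any(effect_metabolites <= 0)) {
      bad("effect_metabolites",
          "must be a named numeric vector of multipliers > 0")
    }
  }
  structure(config, class = "simulation_config")
}

# Default planted-effect plan: 19 increased, 12 decreased metabolites, on the
# generic metabolite names used by simulate_panel().
default_effects <- function(n_metabolites) {
  nm <- panel_metabolite_names(n_metabolites)
  n_up <- min(19L, max(0L, n_metabolites - 2L))
  n_dn <- min(12L, max(0L, n_metabolites - 2L - n_up))
  eff <- c(
    setNames(seq(1.4, 2.2, length.out = n_up), nm[seq_len(n_up) + 1L]),
    setNames(seq(0.45, 0.8, length.out = n_dn), nm[seq_len(n_dn) + 1L + n_up])
  )
  eff
}

panel_metabolite_names <- function(n_metabolites) {
  c("glutathione", sprintf("met_%03d", seq_len(n_metabolites - 1L)))
}

# Latent Gaussian correlation that yields Pearson correlation r_target between
# two lognormal variables with log-scale standard deviations s1, s2
# (moment inversion of the bivariate-lognormal correlation formula).
lognormal_latent_rho <- function(r_target, s1, s2) {
  if (s1 == 0 || s2 == 0) return(r_target)
  rho <- log(1 + r_target * sqrt(expm1(s1^2) * expm1(s2^2))) / (s1 * s2)
  if (!is.finite(rho) || abs(rho) > 1) {
    stop_input(
      "requested correlation target is not attainable for lognormal marginals with these spreads",
      class = "metresist_config_error"
    )
  }
  rho
}

#' Simulate a full cell-line panel bundle with planted effects
#'
#' Generates a metabolite concentration panel (control/treated, replicated), a
#' phenotype table (lineage, doubling time, IC50 at 48 h and 96 h), a log2
#' expression matrix and a gene-set collection, together with a `truth` record
#' of everything that was planted. Baseline concentrations are lognormal
#' (positive, right-skewed, as NMR-quantified metabolite levels are); treated
#' replicate means equal control means times the planted multiplicative
#' effect; phenotype correlations are planted through shared latent Gaussian
#' factors with the latent correlation solved so the natural-scale Pearson
#' correlation matches the target in expectation.
#'
#' @param config A [simulation_config()].
#' @returns A list of class `"panel_bundle"` with elements
#'   `metabolite_panel` (long tibble: cell_line, metabolite, condition,
#'   replicate, concentration), `phenotypes` (tibble), `expression` (wide
#'   tibble, first column `gene_symbol`), `gene_sets` (named list of gene
#'   symbol vectors) and `truth` (list of planted effects).
#' @examples
#' bundle <- simulate_panel(simulation_config(seed = 42))
#' dplyr::count(bundle$metabolite_panel, condition)
#' @export
simulate_panel <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  set.seed(config$seed)

  n_cl <- config$n_cell_lines
  cell_lines <- sprintf("CL%03d", seq_len(n_cl))
  n_bcp <- round(n_cl * 6 / 13)
  lineage <- c(rep("BCP-ALL", n_bcp), rep("T-ALL", n_cl - n_bcp))

  metabolites <- panel_metabolite_names(config$n_metabolites)
  effects <- config$effect_metabolites %||% default_effects(config$n_metabolites)
  unknown <- setdiff(names(effects), metabolites)
  if (length(unknown) > 0) {
    stop_input(sprintf(
      "invalid simulation config: field 'effect_metabolites' names unknown metabolites: %s",
      paste(unknown, collapse = ", ")), class = "metresist_config_error")
  }

  # --- latent factors ------------------------------------------------------
  z_res <- rnorm(n_cl)     # resistance factor (drives late IC50 and GSH)
  z_prol <- rnorm(n_cl)    # proliferation factor (drives doubling time, early IC50)

  rng <- log(config$ic50_range_nM)
  m96 <- mean(rng); s96 <- diff(rng) / 4
  ic50_96 <- exp(m96 + s96 * z_res)

  dt_rng <- log(c(1, 3))   # doubling times of 1-3 days, typical of leukemia lines
  mdt <- mean(dt_rng); sdt <- diff(dt_rng) / 4
  doubling <- exp(mdt + sdt * z_prol)

  rng48 <- log(config$ic50_48_range_nM)
  m48 <- mean(rng48); s48 <- diff(rng48) / 4
  rho_p <- lognormal_latent_rho(config$prolif_corr_target, sdt, s48)
  ic50_48 <- exp(m48 + s48 * (rho_p * z_prol +
                                sqrt(1 - rho_p^2) * rnorm(n_cl)))

  phenotypes <- tibble(
    cell_line = cell_lines,
    lineage = lineage,
    doubling_time_days = doubling,
    mtx_ic50_48_nM = ic50_48,
    mtx_ic50_96_nM = ic50_96
  )

  # --- metabolite panel ----------------------------------------------------
  sigma_cell <- 0.3  # between-cell-line spread on the log scale
  rho_g <- lognormal_latent_rho(config$resistance_corr_target, sigma_cell, s96)
  gsh_latent <- rho_g * z_res + sqrt(1 - rho_g^2) * rnorm(n_cl)

  mu_met <- runif(config$n_metabolites, log(0.05), log(10))
  names(mu_met) <- metabolites

  cell_dev <- matrix(rnorm(n_cl * config$n_metabolites, sd = sigma_cell),
                     nrow = n_cl,
                     dimnames = list(cell_lines, metabolites))
  cell_dev[, "glutathione"] <- sigma_cell * gsh_latent

  base_level <- exp(sweep(cell_dev, 2, mu_met, `+`))  # cell line x metabolite

  sl <- sqrt(log(1 + config$replicate_cv^2))
  n_rep <- config$n_replicates
  grid <- tidyr::expand_grid(
    cell_line = cell_lines,
    metabolite = metabolites,
    condition = c("control", "treated"),
    replicate = seq_len(n_rep)
  )
  eff_vec <- setNames(rep(1, length(metabolites)), metabolites)
  eff_vec[names(effects)] <- effects
  base <- base_level[cbind(grid$cell_line, grid$metabolite)]
  eff <- ifelse(grid$condition == "treated", eff_vec[grid$metabolite], 1)
  noise <- if (sl > 0) rlnorm(nrow(grid), meanlog = -sl^2 / 2, sdlog = sl) else 1
  panel <- dplyr::mutate(grid, concentration = base * eff * noise)

  # --- expression matrix and gene sets -------------------------------------
  n_genes <- config$n_genes
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  set_size <- min(30L, max(2L, floor(n_genes / 3)))
  planted_genes <- genes[seq_len(set_size)]
  beta <- config$gene_set_corr
  mu_g <- runif(n_genes, 4, 12)

  x <- (gsh_latent - mean(gsh_latent)) / (sd(gsh_latent) %||% 1)
  expr_mat <- matrix(rnorm(n_genes * n_cl), nrow = n_genes,
                     dimnames = list(genes, cell_lines))
  expr_mat[seq_len(set_size), ] <-
    beta * matrix(x, nrow = set_size, ncol = n_cl, byrow = TRUE) +
    sqrt(1 - beta^2) * expr_mat[seq_len(set_size), ]
  expr_mat <- expr_mat + mu_g

  expression <- dplyr::bind_cols(
    tibble(gene_symbol = genes),
    as_tibble(expr_mat)
  )

  gene_sets <- list(GSH_METABOLISM = planted_genes)
  n_bg <- max(0L, config$n_gene_sets - 1L)
  bg_pool <- setdiff(genes, planted_genes)
  if (n_bg > 0 && length(bg_pool) >= 15) {
    for (i in seq_len(n_bg)) {
      sz <- sample(15:min(40L, length(bg_pool)), 1)
      gene_sets[[sprintf("RANDOM_SET_%02d", i)]] <- sort(sample(bg_pool, sz))
    }
  }

  truth <- list(
    effect_metabolites = effects,
    gsh_metabolite = "glutathione",
    resistance_corr_target = config$resistance_corr_target,
    prolif_corr_target = config$prolif_corr_target,
    enriched_set = "GSH_METABOLISM",
    lambda = config$lambda,
    seed = config$seed
  )

  structure(
    list(metabolite_panel = panel, phenotypes = phenotypes,
         expression = expression, gene_sets = gene_sets, truth = truth,
         config = config),
    class = "panel_bundle"
  )
}

#' @export
print.panel_bundle <- function(x, ...) {
  cat("<panel_bundle>\n")
  cat(sprintf("  %d cell lines x %d metabolites, %d replicates/condition\n",
              x$config$n_cell_lines, x$config$n_metabolites,
              x$config$n_replicates))
  cat(sprintf("  %d genes, %d gene sets (planted: %s)\n",
              x$config$n_genes, length(x$gene_sets), x$truth$enriched_set))
  cat(sprintf("  planted effects on %d metabolites; GSH~IC50(96h) target r = %.2f\n",
              length(x$truth$effect_metabolites),
              x$truth$resistance_corr_target))
  invisible(x)
}

# Time-resolved potency: a single IC50 is constant in time; a 48h/96h anchor
# pair decays geometrically between (and beyond) the two assay horizons.
ic50_at_time <- function(ic50, t) {
  if (length(ic50) == 1) return(rep(ic50, length(t)))
  ic50[1] * (ic50[2] / ic50[1])^((t - 48) / 48)
}

#' Simulate a dose-time viability surface
#'
#' Live fraction follows a Hill curve `f(c, t) = 1 / (1 + (c / IC50(t))^h)`,
#' multiplied by lognormal measurement noise and clipped to `[0, 1]`.
#'
#' @param ic50 Either a single IC50 (constant potency over time) or a length-2
#'   vector `c(ic50_48h, ic50_96h)`; with two anchors, IC50(t) interpolates
#'   geometrically in time (non-increasing when `ic50[2] <= ic50[1]`).
#' @param hill_slope Hill coefficient (> 0).
#' @param doses Strictly increasing positive dose grid.
#' @param times Non-negative, non-decreasing time grid (hours).
#' @param noise_cv Coefficient of variation of multiplicative lognormal noise.
#' @param seed Optional integer seed.
#' @param drug,cell_line Labels stored in the output.
#' @param n_replicates Replicates per dose-time point. Default 1.
#' @param dose_units Dose unit label. Default `"nM"`.
#' @returns A tibble of class `"viability_surface"` with columns `drug`,
#'   `cell_line`, `dose`, `dose_units`, `time_h`, `replicate`,
#'   `live_fraction`.
#' @examples
#' simulate_viability(10, 1, doses = c(1, 10, 100), times = c(48, 96))
#' @export
simulate_viability <- function(ic50, hill_slope, doses, times,
                               noise_cv = 0, seed = NULL,
                               drug = "drug", cell_line = "cell_line",
                               n_replicates = 1, dose_units = "nM") {
  if (length(doses) == 0 || length(times) == 0) {
    stop_input("doses and times must be non-empty",
               class = "metresist_input_error")
  }
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    stop_input("doses must be strictly increasing and > 0",
               class = "metresist_input_error")
  }
  if (any(times < 0) || is.unsorted(times)) {
    stop_input("times must be non-negative and non-decreasing",
               class = "metresist_input_error")
  }
  if (!is.numeric(ic50) || !length(ic50) %in% c(1, 2) || any(ic50 <= 0)) {
    stop_input("ic50 must be one positive value or a 48h/96h anchor pair",
               class = "metresist_input_error")
  }
  if (hill_slope <= 0) {
    stop_input("hill_slope must be > 0", class = "metresist_input_error")
  }
  if (!is.null(seed)) set.seed(seed)

  grid <- tidyr::expand_grid(
    drug = drug, cell_line = cell_line, dose = doses, dose_units = dose_units,
    time_h = times, replicate = seq_len(n_replicates)
  )
  ic <- ic50_at_time(ic50, grid$time_h)
  f <- 1 / (1 + (grid$dose / ic)^hill_slope)
  if (noise_cv > 0) {
    sl <- sqrt(log(1 + noise_cv^2))
    f <- f * rlnorm(length(f), meanlog = -sl^2 / 2, sdlog = sl)
  }
  out <- dplyr::mutate(grid, live_fraction = pmin(1, pmax(0, f)))
  class(out) <- c("viability_surface", class(out))
  out
}

#' Simulate a fixed-ratio combination surface with a known synergy offset
#'
#' The combination's live fraction along the fixed-ratio ray at ray dose `c`
#' equals the Bliss-additive prediction evaluated at dose `c * 2^lambda`, so
#' the true log2 LD50-ratio synergy score equals `lambda` by construction;
#' `lambda = 0` reproduces the additive surface exactly.
#'
#' @param single_a,single_b Single-agent `"viability_surface"` tibbles sharing
#'   a time grid.
#' @param ratio Fixed concentration ratio `c_b / c_a` (> 0).
#' @param lambda Synergy offset on the log2 dose axis (positive = synergy).
#' @param seed Optional integer seed for the measurement noise.
#' @param noise_cv Coefficient of variation of multiplicative noise. Default 0.
#' @param ray_doses Dose grid along the ray (drug-A reference axis); defaults
#'   to drug A's dose grid.
#' @returns A `"viability_surface"` tibble for the combination, on the drug-A
#'   reference dose axis.
#' @seealso [bliss_additive_surface()], [synergy_score()]
#' @export
simulate_combination <- function(single_a, single_b, ratio, lambda,
                                 seed = NULL, noise_cv = 0, ray_doses = NULL) {
  design <- combination_design(
    drug_a = single_a$drug[1], drug_b = single_b$drug[1],
    ratio_rho = ratio, dose_reference = "drug_a"
  )
  ray_doses <- ray_doses %||% sort(unique(single_a$dose))
  shifted <- bliss_additive_surface(single_a, single_b, design,
                                    ray_doses = ray_doses * 2^lambda)
  if (!is.null(seed)) set.seed(seed)
  f <- shifted$live_fraction
  if (noise_cv > 0) {
    sl <- sqrt(log(1 + noise_cv^2))
    f <- f * rlnorm(length(f), meanlog = -sl^2 / 2, sdlog = sl)
  }
  out <- dplyr::mutate(
    shifted,
    dose = rep(ray_doses, each = nrow(shifted) / length(ray_doses)),
    live_fraction = pmin(1, pmax(0, f))
  )
  class(out) <- c("viability_surface", class(out))
  out
}
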