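#' Fixed-ratio combination design
#'
#' Describes a fixed-concentration-ratio combination ray: along the ray, the
#' two component doses keep a constant ratio `ratio_rho = c_b / c_a`. Ray
#' doses can be referenced either to drug A's concentration (default) or to
#' the total concentration `c_a + c_b`.
#'
#' @param drug_a,drug_b Drug labels.
#' @param ratio_rho Concentration ratio `c_b / c_a` (> 0).
#' @param dose_reference `"drug_a"` or `"total"`.
#' @param ray_doses Optional strictly increasing positive ray dose grid.
#' @returns A list of class `"combination_design"`.
#' @export
combination_design <- function(drug_a, drug_b, ratio_rho,
                               dose_reference = c("drug_a", "total"),
                               ray_doses = NULL) {
  dose_reference <- match.arg(dose_reference)
  if (!is_scalar_number(ratio_rho) || ratio_rho <= 0) {
    stop_input("ratio_rho must be a positive number",
               class = "metresist_input_error")
  }
  if (!is.null(ray_doses)) {
    if (any(ray_doses <= 0) || is.unsorted(ray_doses, strictly = TRUE)) {
      stop_input("ray_doses must be strictly increasing and > 0",
                 class = "metresist_input_error")
    }
  }
  structure(
    list(drug_a = drug_a, drug_b = drug_b, ratio_rho = ratio_rho,
         dose_reference = dose_reference, ray_doses = ray_doses),
    class = "combination_design"
  )
}

# Component doses implied by a ray dose under the design's reference axis.
component_doses <- function(design, ray_dose) {
  rho <- design$ratio_rho
  if (design$dose_reference == "drug_a") {
    list(a = ray_dose, b = rho * ray_dose)
  } else {
    list(a = ray_dose / (1 + rho), b = rho * ray_dose / (1 + rho))
  }
}

check_time_alignment <- function(f_a, f_b) {
  ta <- sort(unique(f_a$time_h))
  tb <- sort(unique(f_b$time_h))
  if (length(ta) != length(tb) || any(ta != tb)) {
    stop_input("single-agent surfaces must share a time grid",
               class = "metresist_alignment_error")
  }
  ta
}

#' Bliss-independence additive reference surface along a fixed-ratio ray
#'
#' The Bliss additive prediction composes *surviving* fractions
#' multiplicatively: at ray dose `c` and time `t`, the predicted live fraction
#' is `f_a(c_a, t) * f_b(c_b, t)` with `(c_a, c_b)` the component doses
#' implied by the design. (On fractions affected this is the usual
#' `E_a + E_b - E_a * E_b`.) Single-agent fractions are evaluated by linear
#' interpolation of replicate-mean live fraction against log10 dose, with
#' constant extrapolation beyond the measured grid; extrapolated evaluations
#' are flagged in the `extrapolated` column and trigger a warning.
#'
#' @param f_a,f_b Single-agent `"viability_surface"` tibbles on a shared time
#'   grid (same cell line).
#' @param design A [combination_design()].
#' @param ray_doses Ray dose grid; defaults to the design's, else to drug A's
#'   measured doses mapped to the reference axis.
#' @returns A `"viability_surface"` tibble (one replicate) with the predicted
#'   additive live fraction and an `extrapolated` flag, rows ordered dose-major.
#' @examples
#' a <- simulate_viability(10, 1, c(1, 10, 100), 96, drug = "A")
#' b <- simulate_viability(10, 1, c(1, 10, 100), 96, drug = "B")
#' d <- combination_design("A", "B", ratio_rho = 1)
#' bliss_additive_surface(a, b, d)
#' @export
bliss_additive_surface <- function(f_a, f_b, design, ray_doses = NULL) {
  times <- check_time_alignment(f_a, f_b)
  ray_doses <- ray_doses %||% design$ray_doses
  if (is.null(ray_doses)) {
    base <- sort(unique(f_a$dose[f_a$dose > 0]))
    ray_doses <- if (design$dose_reference == "total") {
      base * (1 + design$ratio_rho)
    } else {
      base
    }
  }
  comp <- component_doses(design, ray_doses)

  rows <- purrr::map(times, function(t) {
    sa <- surface_slice(f_a, t)
    sb <- surface_slice(f_b, t)
    ia <- interp_log_dose(sa$dose[sa$dose > 0],
                          sa$live_fraction[sa$dose > 0], comp$a)
    ib <- interp_log_dose(sb$dose[sb$dose > 0],
                          sb$live_fraction[sb$dose > 0], comp$b)
    tibble(
      dose = ray_doses, time_h = t,
      live_fraction = ia$value * ib$value,
      extrapolated = ia$extrapolated | ib$extrapolated
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$dose, .data$time_h) |>
    dplyr::mutate(
      drug = paste(design$drug_a, design$drug_b, sep = "+"),
      cell_line = f_a$cell_line[1],
      dose_units = if ("dose_units" %in% names(f_a)) f_a$dose_units[1] else NA_character_,
      replicate = 1L,
      .before = 1
    ) |>
    dplyr::relocate("dose", "dose_units", "time_h", "replicate",
                    .after = "cell_line")
  if (any(out$extrapolated)) {
    rlang::warn(sprintf(
      "Bliss surface: %d ray point(s) required extrapolation beyond a single-agent dose grid",
      sum(out$extrapolated)))
  }
  class(out) <- c("viability_surface", class(out))
  out
}

#' Log2 LD50-ratio synergy score against the Bliss additive reference
#'
#' Computes the additive LD50 (median-effect dose of the Bliss additive
#' surface built from the two single agents) and the measured combination
#' LD50 at the same time slice and on the same reference dose axis, and
#' scores the interaction as `log2(LD50_additive / LD50_combination)`:
#' positive means the combination kills at lower doses than additivity
#' predicts (synergy), negative means antagonism. When an LD50 is censored
#' (its curve never crosses 50% viability within the tested range), the score
#' is censored too, with a directional bound on the score where one is
#' implied.
#'
#' @param f_a,f_b Single-agent `"viability_surface"` tibbles.
#' @param f_combo Combination surface measured along the design ray (doses on
#'   the design's reference axis).
#' @param design A [combination_design()].
#' @param t Time (hours); default is the latest common time point.
#' @param method LD50 estimation method, passed to [estimate_ic50()].
#' @param threshold Synergy call threshold passed to [classify_interaction()].
#' @returns A one-row tibble of class `"synergy_result"`: `drug_a`, `drug_b`,
#'   `cell_line`, `time_h`, `ratio_rho`, `dose_reference`, `ld50_additive`,
#'   `ld50_combination`, `score`, `censored`, `bound_type` (`"none"`, `"ge"`,
#'   `"le"`), `bound_value`, `call`.
#' @export
synergy_score <- function(f_a, f_b, f_combo, design, t = NULL,
                          method = c("auto", "fit", "interp"),
                          threshold = 0.25) {
  method <- match.arg(method)
  times <- check_time_alignment(f_a, f_b)
  t <- t %||% max(intersect(times, unique(f_combo$time_h)))
  if (!is_scalar_number(t)) {
    stop_input("no common time point between singles and combination",
               class = "metresist_alignment_error")
  }
  combo_doses <- sort(unique(f_combo$dose[f_combo$dose > 0]))
  additive <- bliss_additive_surface(f_a, f_b, design, ray_doses = combo_doses)
  ld_add <- ld50_at_time(additive, t, method = method)
  ld_combo <- ld50_at_time(f_combo, t, method = method)

  dmin <- min(combo_doses); dmax <- max(combo_doses)
  score <- NA_real_
  bound_type <- "none"; bound_value <- NA_real_
  censored <- "none"
  if (ld_add$censored == "none" && ld_combo$censored == "none") {
    score <- log2(ld_add$ic50 / ld_combo$ic50)
  } else {
    censored <- paste(
      c(if (ld_add$censored != "none") paste0("additive_", ld_add$censored),
        if (ld_combo$censored != "none") paste0("combination_", ld_combo$censored)),
      collapse = ";")
    if (ld_add$censored == "none") {
      # combination LD50 outside its range bounds the score
      if (ld_combo$censored == "above_max") {
        bound_type <- "le"; bound_value <- log2(ld_add$ic50 / dmax)
      } else {
        bound_type <- "ge"; bound_value <- log2(ld_add$ic50 / dmin)
      }
    } else if (ld_combo$censored == "none") {
      if (ld_add$censored == "above_max") {
        bound_type <- "ge"; bound_value <- log2(dmax / ld_combo$ic50)
      } else {
        bound_type <- "le"; bound_value <- log2(dmin / ld_combo$ic50)
      }
    }
  }

  out <- tibble(
    drug_a = design$drug_a, drug_b = design$drug_b,
    cell_line = f_combo$cell_line[1], time_h = t,
    ratio_rho = design$ratio_rho, dose_reference = design$dose_reference,
    ld50_additive = if (ld_add$censored == "none") ld_add$ic50 else NA_real_,
    ld50_combination = if (ld_combo$censored == "none") ld_combo$ic50 else NA_real_,
    score = score, censored = censored,
    bound_type = bound_type, bound_value = bound_value
  )
  out <- classify_interaction(out, threshold = threshold)
  class(out) <- c("synergy_result", class(out))
  out
}

#' Call synergy, additivity or antagonism from a synergy score
#'
#' Scores above `threshold` are called synergy, below `-threshold`
#' antagonism, otherwise additive. A censored score with a directional bound
#' is called when the bound is decisive (e.g. "score >= 0.4" with threshold
#' 0.25 is synergy) and `NA` otherwise.
#'
#' @param result A `"synergy_result"` tibble (or any tibble with `score`,
#'   `bound_type`, `bound_value` columns).
#' @param threshold Non-negative call threshold on the log2 score scale.
#'   Default 0.25.
#' @returns The input with the `call` column set.
#' @export
classify_interaction <- function(result, threshold = 0.25) {
  if (!is_scalar_number(threshold) || threshold < 0) {
    stop_input("threshold must be >= 0", class = "metresist_input_error")
  }
  call_one <- function(score, bound_type, bound_value) {
    if (is.finite(score)) {
      if (score > threshold) return("synergy")
      if (score < -threshold) return("antagonism")
      return("additive")
    }
    if (bound_type == "ge" && is.finite(bound_value) && bound_value > threshold) {
      return("synergy")
    }
    if (bound_type == "le" && is.finite(bound_value) && bound_value < -threshold) {
      return("antagonism")
    }
    NA_character_
  }
  result$call <- purrr::pmap_chr(
    list(result$score, result$bound_type, result$bound_value), call_one)
  result
}
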