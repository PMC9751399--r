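#' Normalize raw viability signals to live fractions
#'
#' Converts raw well signals (fluorescence sums, absorbance, or bead-normalized
#' flow-cytometry counts) to live fractions relative to the vehicle and death
#' controls: `(raw - death_mean) / (vehicle_mean - death_mean)`, clipped to
#' `[0, 1]`.
#'
#' @param raw A data frame with columns `drug`, `cell_line`, `dose`, `time_h`,
#'   `replicate` and a raw signal column named by `value_col`. A `dose_units`
#'   column is carried through if present.
#' @param vehicle_mean Mean signal of the vehicle (negative) control.
#' @param death_mean Mean signal of the death (positive) control.
#' @param value_col Name of the raw signal column. Default `"value"`.
#' @returns A `"viability_surface"` tibble with a `live_fraction` column.
#' @examples
#' raw <- tibble::tibble(drug = "d", cell_line = "c", dose = c(1, 10),
#'                       time_h = 48, replicate = 1, value = c(900, 300))
#' normalize_viability(raw, vehicle_mean = 1000, death_mean = 100)
#' @export
normalize_viability <- function(raw, vehicle_mean, death_mean,
                                value_col = "value") {
  if (!is_scalar_number(vehicle_mean) || !is_scalar_number(death_mean) ||
      vehicle_mean <= death_mean) {
    stop_input(
      "vehicle control mean must exceed death control mean (controls inverted?)",
      class = "metresist_control_inversion_error"
    )
  }
  check_columns(raw, c("drug", "cell_line", "dose", "time_h", "replicate",
                       value_col), "viability table")
  frac <- (raw[[value_col]] - death_mean) / (vehicle_mean - death_mean)
  out <- as_tibble(raw)
  out[[value_col]] <- NULL
  out$live_fraction <- pmin(1, pmax(0, frac))
  if (!"dose_units" %in% names(out)) out$dose_units <- NA_character_
  out <- dplyr::relocate(out, "live_fraction", .after = dplyr::last_col())
  class(out) <- c("viability_surface", class(out))
  out
}

#' Estimate the half-maximal concentration from a dose-response profile
#'
#' The primary method fits a four-parameter logistic (4PL) model on log10
#' dose with bounded parameters (top <= 1.05, bottom >= -0.05, slope > 0) by
#' Levenberg-Marquardt least squares; the reported IC50 is the dose at which
#' the fitted curve crosses a live fraction of 0.5 (median effect). When the
#' fit fails to converge, the estimate falls back to monotone log-linear
#' interpolation of the first downward 0.5 crossing. When the observed
#' fractions never bracket 0.5 within the tested range, the estimate is
#' censored (`above_max` when viability stays above 0.5, `below_min` when it
#' stays below) rather than raising an error.
#'
#' @param doses Positive dose vector (zero/vehicle entries are dropped).
#' @param fractions Mean live fractions in `[0, 1]`, same length as `doses`.
#' @param method `"auto"` (fit, falling back to interpolation), `"fit"`, or
#'   `"interp"`.
#' @returns An object of class `"potency_estimate"`: a list with elements
#'   `ic50`, `censored` (`"none"`, `"above_max"`, `"below_min"`), `method`
#'   (`"fit"` or `"interpolation"`), `auc` (normalized log-dose area, in
#'   `[0, 1]`), `fit` (the `nls` object or `NULL`) and `data`.
#' @examples
#' d <- c(1, 3, 9, 27, 81)
#' f <- 1 / (1 + d / 10)
#' estimate_ic50(d, f)
#' @export
estimate_ic50 <- function(doses, fractions, method = c("auto", "fit", "interp")) {
  method <- match.arg(method)
  keep <- doses > 0 & !is.na(fractions)
  doses <- doses[keep]; fractions <- fractions[keep]
  if (length(doses) < 2) {
    stop_input("at least 2 positive doses are required",
               class = "metresist_input_error")
  }
  if (any(fractions < -1e-8) || any(fractions > 1 + 1e-8)) {
    stop_input("fractions must lie in [0, 1]; normalize first",
               class = "metresist_input_error")
  }
  ord <- order(doses)
  doses <- doses[ord]; fractions <- pmin(1, pmax(0, fractions[ord]))

  auc <- auc_log_dose(doses, fractions)
  base <- list(ic50 = NA_real_, censored = "none", method = NA_character_,
               auc = auc, fit = NULL,
               data = tibble(dose = doses, live_fraction = fractions))

  if (min(fractions) > 0.5) {
    base$censored <- "above_max"
    return(structure(base, class = "potency_estimate"))
  }
  if (max(fractions) < 0.5) {
    base$censored <- "below_min"
    return(structure(base, class = "potency_estimate"))
  }
  if (max(fractions) == min(fractions)) {
    # flat at exactly 0.5: no information about a crossing
    base$censored <- "above_max"
    return(structure(base, class = "potency_estimate"))
  }

  if (method %in% c("auto", "fit")) {
    fit <- fit_4pl(doses, fractions)
    if (!is.null(fit)) {
      ic50 <- crossing_from_4pl(fit)
      if (is.finite(ic50) && ic50 > 0) {
        base$ic50 <- ic50
        base$method <- "fit"
        base$fit <- fit
        return(structure(base, class = "potency_estimate"))
      }
    }
    if (method == "fit") {
      rlang::warn("4PL fit did not yield a median-effect crossing; falling back to interpolation")
    }
  }

  base$ic50 <- interp_crossing(doses, fractions)
  base$method <- "interpolation"
  structure(base, class = "potency_estimate")
}

# Bounded 4PL fit on log10 dose; returns NULL on failure. A start exactly at
# a symmetric configuration can make the initial Jacobian singular, so a few
# nudged starting points are tried in order.
fit_4pl <- function(doses, fractions) {
  lx <- log10(doses)
  start_le <- tryCatch(log10(interp_crossing(doses, fractions)),
                       error = function(e) mean(lx))
  if (!is.finite(start_le)) start_le <- mean(lx)
  lower <- c(top = 0.5, bottom = -0.05, le = min(lx) - 3, h = 0.05)
  upper <- c(top = 1.05, bottom = 0.45, le = max(lx) + 3, h = 20)
  span <- max(diff(range(lx)), 1)
  starts <- list(
    list(le = start_le, h = 1),
    list(le = start_le + 0.05 * span, h = 1.2),
    list(le = start_le - 0.05 * span, h = 0.7),
    list(le = mean(lx) + 0.02 * span, h = 2)
  )
  for (s in starts) {
    start <- list(top = min(max(max(fractions), lower[["top"]]), 1.05),
                  bottom = max(min(min(fractions), upper[["bottom"]]), -0.05),
                  le = min(max(s$le, lower[["le"]]), upper[["le"]]),
                  h = s$h)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fractions ~ bottom + (top - bottom) / (1 + 10^(h * (lx - le))),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) return(fit)
  }
  NULL
}

crossing_from_4pl <- function(fit) {
  p <- as.list(coef(fit))
  rhs <- (p$top - 0.5) / (0.5 - p$bottom)
  if (!is.finite(rhs) || rhs <= 0) return(NA_real_)
  10^(p$le + log10(rhs) / p$h)
}

# First downward 0.5 crossing, linear in live fraction vs log10 dose.
interp_crossing <- function(doses, fractions) {
  lx <- log10(doses)
  hit <- which(fractions == 0.5)
  if (length(hit) > 0) return(10^(lx[hit[1]]))
  for (i in seq_len(length(doses) - 1)) {
    f1 <- fractions[i]; f2 <- fractions[i + 1]
    if ((f1 - 0.5) * (f2 - 0.5) < 0) {
      l50 <- lx[i] + (0.5 - f1) / (f2 - f1) * (lx[i + 1] - lx[i])
      return(10^l50)
    }
  }
  stop_input("fractions never cross 0.5 between adjacent doses",
             class = "metresist_input_error")
}

# Trapezoidal area of live fraction vs log10 dose, normalized by the log-dose
# span so that 1 means no kill anywhere and 0 means complete kill.
auc_log_dose <- function(doses, fractions) {
  lx <- log10(doses)
  span <- diff(range(lx))
  if (span == 0) return(mean(fractions))
  area <- sum(diff(lx) * (head(fractions, -1) + fractions[-1]) / 2)
  area / span
}

#' @export
print.potency_estimate <- function(x, ...) {
  cat("<potency_estimate>\n")
  if (x$censored == "none") {
    cat(sprintf("  ic50 = %.4g (%s), auc = %.3f, %d doses\n",
                x$ic50, x$method, x$auc, nrow(x$data)))
  } else {
    cat(sprintf("  censored (%s), auc = %.3f, %d doses\n",
                x$censored, x$auc, nrow(x$data)))
  }
  invisible(x)
}

#' Median-effect dose (LD50) at a time slice of a viability surface
#'
#' Takes the time slice nearest `t` (ties resolved toward the later time),
#' averages replicates per dose, and applies [estimate_ic50()].
#'
#' @param surface A `"viability_surface"` tibble.
#' @param t Time in hours; must lie within the surface's time range.
#' @param method Passed to [estimate_ic50()].
#' @returns A `"potency_estimate"`.
#' @export
ld50_at_time <- function(surface, t, method = c("auto", "fit", "interp")) {
  slice <- surface_slice(surface, t)
  estimate_ic50(slice$dose, slice$live_fraction, method = match.arg(method))
}

surface_slice <- function(surface, t) {
  check_columns(surface, c("dose", "time_h", "live_fraction"),
                "viability surface")
  if (nrow(surface) == 0) {
    stop_input("empty viability surface", class = "metresist_input_error")
  }
  if (t < min(surface$time_h) || t > max(surface$time_h)) {
    stop_input(sprintf("time %s h is outside the surface's range [%s, %s]",
                       t, min(surface$time_h), max(surface$time_h)),
               class = "metresist_input_error")
  }
  tt <- nearest_time(surface$time_h, t)
  surface |>
    dplyr::filter(.data$time_h == tt) |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(live_fraction = mean(.data$live_fraction),
                     .groups = "drop") |>
    dplyr::arrange(.data$dose)
}

#' Normalized dose-axis area under the viability curve at a time slice
#'
#' Trapezoidal area of mean live fraction against log10 dose at the time slice
#' nearest `t`, divided by the log-dose span, so the value lies in `[0, 1]`
#' (1 = no kill at any dose; 0 = complete kill everywhere).
#'
#' @inheritParams ld50_at_time
#' @returns A single number in `[0, 1]`.
#' @export
auc_dose <- function(surface, t) {
  slice <- surface_slice(surface, t)
  slice <- dplyr::filter(slice, .data$dose > 0)
  if (nrow(slice) < 2) {
    stop_input("at least 2 positive doses are required for a dose-axis AUC",
               class = "metresist_input_error")
  }
  auc_log_dose(slice$dose, slice$live_fraction)
}

#' Doubling time from a proliferation curve
#'
#' Fits ordinary least squares to log2(count) versus time (days) on replicate
#' means; the doubling time is the reciprocal slope.
#'
#' @param curve Data frame with columns `time_days` and `count` (cells/ml,
#'   > 0), optionally `replicate`.
#' @returns A one-row tibble with `n_points`, `slope_per_day` and
#'   `doubling_time_days`.
#' @examples
#' doubling_time(tibble::tibble(time_days = 0:2, count = c(1e5, 2e5, 4e5)))
#' @export
doubling_time <- function(curve) {
  check_columns(curve, c("time_days", "count"), "growth curve")
  if (any(curve$count <= 0)) {
    stop_input("counts must be > 0", class = "metresist_input_error")
  }
  means <- curve |>
    dplyr::group_by(.data$time_days) |>
    dplyr::summarise(count = mean(.data$count), .groups = "drop")
  if (nrow(means) < 3) {
    stop_input("at least 3 distinct time points are required",
               class = "metresist_input_error")
  }
  fit <- lm(log2(count) ~ time_days, data = means)
  slope <- unname(coef(fit)[["time_days"]])
  if (!is.finite(slope) || slope <= 0) {
    stop_input("non-positive growth slope: culture is not growing",
               class = "metresist_nongrowing_error")
  }
  tibble(n_points = nrow(means), slope_per_day = slope,
         doubling_time_days = 1 / slope)
}
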