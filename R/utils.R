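# Internal helpers shared across modules.

stop_input <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "metresist_error"), ...)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "metresist_schema_error"
    )
  }
  invisible(df)
}

#' Linear interpolation of a response against log10 dose
#'
#' Interpolates live fractions linearly in log10(dose); outside the grid the
#' boundary value is carried constant and the result is flagged as
#' extrapolated. Serial-dilution designs are geometric, so log-dose is the
#' natural interpolation axis.
#'
#' @param doses Strictly positive dose grid (need not be sorted).
#' @param fractions Response values at `doses`.
#' @param at Doses at which to evaluate.
#' @returns A list with `value` (interpolated responses) and `extrapolated`
#'   (logical, `TRUE` where `at` fell outside the dose grid).
#' @keywords internal
#' @noRd
interp_log_dose <- function(doses, fractions, at) {
  if (any(doses <= 0) || any(at <= 0)) {
    stop_input("doses must be strictly positive for log-dose interpolation",
               class = "metresist_input_error")
  }
  ord <- order(doses)
  lx <- log10(doses[ord])
  fy <- fractions[ord]
  la <- log10(at)
  out <- approx(lx, fy, xout = la, rule = 2, ties = mean)$y
  list(
    value = out,
    extrapolated = la < min(lx) | la > max(lx)
  )
}

# Nearest time slice; ties resolved toward the later time point.
nearest_time <- function(times, t) {
  ut <- sort(unique(times))
  d <- abs(ut - t)
  candidates <- ut[d == min(d)]
  max(candidates)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
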