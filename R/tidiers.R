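# broom-style methods for fitted objects.

#' Tidy a potency estimate
#'
#' @param x A `"potency_estimate"` from [estimate_ic50()].
#' @param ... Ignored.
#' @returns A one-row tibble: `ic50`, `censored`, `method`, `auc`, `n_doses`.
#' @method tidy potency_estimate
#' @export
tidy.potency_estimate <- function(x, ...) {
  tibble(ic50 = x$ic50, censored = x$censored, method = x$method,
         auc = x$auc, n_doses = nrow(x$data))
}

#' Glance at a potency estimate's fit quality
#'
#' @inheritParams tidy.potency_estimate
#' @returns A one-row tibble with the 4PL parameters (when fitted) and the
#'   residual standard deviation.
#' @method glance potency_estimate
#' @export
glance.potency_estimate <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(top = NA_real_, bottom = NA_real_, log10_ic50 = NA_real_,
                  hill_slope = NA_real_, sigma = NA_real_,
                  method = x$method))
  }
  cf <- as.list(coef(x$fit))
  tibble(top = cf$top, bottom = cf$bottom, log10_ic50 = cf$le,
         hill_slope = cf$h, sigma = summary(x$fit)$sigma, method = x$method)
}

#' Augment dose-response data with 4PL fitted values
#'
#' @inheritParams tidy.potency_estimate
#' @returns The estimate's data with a `.fitted` column (NA when the estimate
#'   came from interpolation).
#' @method augment potency_estimate
#' @export
augment.potency_estimate <- function(x, ...) {
  out <- x$data
  if (is.null(x$fit)) {
    out$.fitted <- NA_real_
  } else {
    cf <- as.list(coef(x$fit))
    out$.fitted <- cf$bottom + (cf$top - cf$bottom) /
      (1 + 10^(cf$h * (log10(out$dose) - cf$le)))
  }
  out
}

#' Tidy a synergy result (already tabular; returned as a plain tibble)
#'
#' @param x A `"synergy_result"`.
#' @param ... Ignored.
#' @returns A tibble.
#' @method tidy synergy_result
#' @export
tidy.synergy_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "synergy_result")
  as_tibble(out)
}

#' Glance at a GSEA run
#'
#' @param x A `"gsea_result"` tibble from [gsea_permutation()].
#' @param ... Ignored.
#' @returns A one-row tibble: number of sets tested and number significant.
#' @method glance gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(n_sets = nrow(x), n_significant = sum(x$significant),
         min_p = if (nrow(x) > 0) min(x$p_nominal) else NA_real_)
}
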