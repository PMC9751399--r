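# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_segment geom_boxplot scale_x_log10 scale_y_log10 labs theme_minimal
#'   facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a dose-response profile with its fitted curve
#'
#' @param object A `"potency_estimate"` from [estimate_ic50()].
#' @param ... Ignored.
#' @returns A ggplot.
#' @method autoplot potency_estimate
#' @export
autoplot.potency_estimate <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$dose, y = .data$live_fraction)) +
    geom_point() +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    scale_x_log10() +
    labs(x = "dose", y = "live fraction",
         title = if (object$censored == "none") {
           sprintf("IC50 = %.3g (%s)", object$ic50, object$method)
         } else {
           sprintf("censored (%s)", object$censored)
         }) +
    theme_minimal()
  if (!is.null(object$fit)) {
    rng <- range(object$data$dose)
    grid <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200)
    cf <- as.list(coef(object$fit))
    pred <- cf$bottom + (cf$top - cf$bottom) /
      (1 + 10^(cf$h * (log10(grid) - cf$le)))
    p <- p + geom_line(data = tibble(dose = grid, live_fraction = pred),
                       colour = "steelblue")
  }
  p
}

#' Plot a viability surface (live fraction vs dose, by time)
#'
#' @param object A `"viability_surface"` tibble.
#' @param ... Ignored.
#' @returns A ggplot.
#' @method autoplot viability_surface
#' @export
autoplot.viability_surface <- function(object, ...) {
  means <- object |>
    dplyr::filter(.data$dose > 0) |>
    dplyr::group_by(.data$drug, .data$dose, .data$time_h) |>
    dplyr::summarise(live_fraction = mean(.data$live_fraction),
                     .groups = "drop")
  ggplot(means, aes(x = .data$dose, y = .data$live_fraction,
                    colour = factor(.data$time_h))) +
    geom_point() + geom_line() +
    scale_x_log10() +
    labs(x = "dose", y = "live fraction", colour = "time (h)") +
    facet_wrap(~drug) +
    theme_minimal()
}

#' Fold-change overview plot of a metabolome screen
#'
#' One point per cell line per metabolite (fold change, log2 axis), metabolites
#' ordered by screening P-value; the unity line marks "no drug effect".
#'
#' @param fc_table Output of [fold_changes()].
#' @param screen Optional output of [metabolome_screen()] used to order
#'   metabolites and colour the direction calls.
#' @param top Show at most this many metabolites (by screen order). Default 30.
#' @returns A ggplot.
#' @export
plot_fold_changes <- function(fc_table, screen = NULL, top = 30) {
  df <- fc_table
  if (!is.null(screen)) {
    ord <- screen$metabolite
    df <- df |>
      dplyr::filter(.data$metabolite %in% head(ord, top)) |>
      dplyr::left_join(screen[c("metabolite", "direction")], by = "metabolite") |>
      dplyr::mutate(metabolite = factor(.data$metabolite, levels = rev(head(ord, top))))
    aes_map <- aes(x = .data$fc, y = .data$metabolite, colour = .data$direction)
  } else {
    df <- dplyr::filter(df, .data$metabolite %in% head(unique(df$metabolite), top))
    aes_map <- aes(x = .data$fc, y = .data$metabolite)
  }
  ggplot(df, aes_map) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    scale_x_log10() +
    labs(x = "fold change (treated / control)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' GSEA running-sum (enrichment score) plot
#'
#' @inheritParams gsea_es
#' @returns A ggplot of the running enrichment score with hit positions marked.
#' @export
plot_gsea_running_sum <- function(ranked, set, weight_p = 1) {
  rs <- gsea_running_sum(ranked, set, weight_p = weight_p)
  es <- gsea_es(ranked, set, weight_p = weight_p)
  tick_h <- diff(range(rs$running_sum)) * 0.08
  ggplot(rs, aes(x = .data$rank, y = .data$running_sum)) +
    geom_line(colour = "forestgreen") +
    geom_hline(yintercept = 0, colour = "grey40") +
    geom_segment(data = dplyr::filter(rs, .data$hit),
                 aes(x = .data$rank, xend = .data$rank,
                     y = min(rs$running_sum) - 1.5 * tick_h,
                     yend = min(rs$running_sum) - 0.5 * tick_h),
                 inherit.aes = FALSE) +
    labs(x = "rank in gene list", y = "running enrichment score",
         title = sprintf("ES = %.3f", es)) +
    theme_minimal()
}
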