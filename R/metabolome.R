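#' Per-cell-line treated/control fold changes of metabolite concentrations
#'
#' For every cell line x metabolite, the fold change is the mean treated
#' concentration over replicates divided by the mean control concentration.
#' Missing replicates are ignored, not imputed.
#'
#' @param panel Long-format metabolite panel: columns `cell_line`,
#'   `metabolite`, `condition` (`"control"` / `"treated"`), `replicate`,
#'   `concentration`.
#' @returns A tibble with columns `cell_line`, `metabolite`, `fc`.
#' @export
fold_changes <- function(panel) {
  check_columns(panel, c("cell_line", "metabolite", "condition", "replicate",
                         "concentration"), "metabolite panel")
  bad_cond <- setdiff(unique(panel$condition), c("control", "treated"))
  if (length(bad_cond) > 0) {
    stop_input(sprintf("unknown condition(s): %s",
                       paste(bad_cond, collapse = ", ")),
               class = "metresist_schema_error")
  }
  means <- panel |>
    dplyr::filter(!is.na(.data$concentration)) |>
    dplyr::group_by(.data$cell_line, .data$metabolite, .data$condition) |>
    dplyr::summarise(m = mean(.data$concentration), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
  if (!all(c("control", "treated") %in% names(means)) ||
      anyNA(means$control) || anyNA(means$treated)) {
    stop_input("both conditions must be present for every cell line x metabolite",
               class = "metresist_input_error")
  }
  zero <- means$control == 0
  if (any(zero)) {
    off <- means[zero, ]
    stop_input(sprintf(
      "undefined fold change (zero control mean) for: %s",
      paste(paste(off$cell_line, off$metabolite, sep = "/"), collapse = ", ")),
      class = "metresist_undefined_fc_error")
  }
  means |>
    dplyr::transmute(.data$cell_line, .data$metabolite,
                     fc = .data$treated / .data$control)
}

#' Exact Wilcoxon signed-rank test of fold changes against unity
#'
#' Tests whether a vector of per-cell-line fold changes systematically
#' deviates from 1. Differences `fc - 1` are ranked by absolute value with
#' midranks for ties; values exactly equal to 1 are dropped. For `n <= 25`
#' usable values the two-sided P comes from the exact null distribution of
#' the positive rank sum over all `2^n` sign assignments (computed by dynamic
#' programming, so midranks are handled exactly); above 25 a normal
#' approximation with continuity and tie corrections is used.
#'
#' @param fc Positive fold-change ratios (one per cell line).
#' @param alpha Significance level used only to set the reported `direction`.
#' @param metabolite Optional label carried into the result.
#' @returns A one-row tibble: `metabolite`, `n_used`, `w_statistic` (the
#'   smaller of the two signed-rank sums), `p_two_sided`, `median_fc`,
#'   `direction` (`"increased"` / `"decreased"` / `"unchanged"`).
#' @examples
#' wilcoxon_vs_unity(c(1.25, 1.5, 0.85, 1.1, 1.3))
#' @export
wilcoxon_vs_unity <- function(fc, alpha = 0.05, metabolite = NA_character_) {
  if (any(fc <= 0) || anyNA(fc)) {
    stop_input("fold changes must be positive and non-missing",
               class = "metresist_input_error")
  }
  d <- fc - 1
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) {
    stop_input(sprintf("need >= 5 fold changes different from 1 (have %d)", n),
               class = "metresist_insufficient_data_error")
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])

  if (n <= 25) {
    p <- signed_rank_exact_p(w_plus, r)
  } else {
    p <- signed_rank_normal_p(w_plus, r)
  }

  med <- median(fc)
  direction <- if (p <= alpha && med > 1) {
    "increased"
  } else if (p <= alpha && med < 1) {
    "decreased"
  } else {
    "unchanged"
  }
  tibble(metabolite = metabolite, n_used = n,
         w_statistic = min(w_plus, w_minus), p_two_sided = p,
         median_fc = med, direction = direction)
}

# Exact two-sided P for the positive signed-rank sum, by convolution over all
# 2^n equally likely sign assignments. Ranks are doubled so midranks become
# integers and the distribution stays exact under ties.
signed_rank_exact_p <- function(w_plus, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (s in r2) {
    shifted <- c(numeric(s), f[seq_len(total + 1 - s)])
    f <- f + shifted
  }
  f <- f / 2^length(r2)
  s_obs <- as.integer(round(2 * w_plus))
  p_lo <- sum(f[seq_len(s_obs + 1)])
  p_hi <- sum(f[(s_obs + 1):(total + 1)])
  min(1, 2 * min(p_lo, p_hi))
}

# Normal approximation with continuity correction and tie correction,
# for n > 25.
signed_rank_normal_p <- function(w_plus, ranks) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  dev <- w_plus - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Screen a metabolite panel for drug-modulated metabolites
#'
#' Runs [fold_changes()] and applies [wilcoxon_vs_unity()] to each
#' metabolite's per-cell-line fold changes.
#'
#' @inheritParams fold_changes
#' @param alpha Significance level for the direction call. Default 0.05 with
#'   no multiple-testing correction (each metabolite is tested marginally).
#' @returns A tibble with one row per metabolite (columns as in
#'   [wilcoxon_vs_unity()]), sorted by P. Metabolites with fewer than 5
#'   usable fold changes are dropped with a warning.
#' @export
metabolome_screen <- function(panel, alpha = 0.05) {
  fc <- fold_changes(panel)
  split_fc <- split(fc$fc, fc$metabolite)
  res <- purrr::imap(split_fc, function(v, m) {
    tryCatch(wilcoxon_vs_unity(v, alpha = alpha, metabolite = m),
             metresist_insufficient_data_error = function(e) NULL)
  })
  dropped <- names(res)[purrr::map_lgl(res, is.null)]
  if (length(dropped) > 0) {
    rlang::warn(sprintf("dropped %d metabolite(s) with < 5 usable fold changes: %s",
                        length(dropped), paste(dropped, collapse = ", ")))
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$p_two_sided)
}

#' Partition screened metabolites into increased and decreased sets
#'
#' @param results Tibble from [metabolome_screen()] (or bound rows of
#'   [wilcoxon_vs_unity()] results), one row per metabolite.
#' @param alpha Significance level; no multiple-testing correction is applied.
#' @returns A list with character vectors `increased` and `decreased` plus the
#'   counts `n_increased` and `n_decreased`.
#' @export
classify_modulated <- function(results, alpha = 0.05) {
  check_columns(results, c("metabolite", "p_two_sided", "median_fc"),
                "screen results")
  if (anyDuplicated(results$metabolite)) {
    stop_input("one result per metabolite expected",
               class = "metresist_input_error")
  }
  sig <- results$p_two_sided <= alpha
  increased <- sort(results$metabolite[sig & results$median_fc > 1])
  decreased <- sort(results$metabolite[sig & results$median_fc < 1])
  list(increased = increased, decreased = decreased,
       n_increased = length(increased), n_decreased = length(decreased))
}

#' Pearson correlation with a two-sided t-test P-value
#'
#' Pairwise-complete sample Pearson correlation; P from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against a t distribution with `n - 2`
#' degrees of freedom. A perfect correlation reports the smallest
#' representable positive P rather than zero.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing member
#'   are dropped.
#' @returns A one-row tibble with `n`, `r`, `p_two_sided`.
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) {
    stop_input("x and y must have equal length", class = "metresist_input_error")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop_input("need at least 3 complete pairs",
               class = "metresist_insufficient_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_input("undefined correlation: zero variance in x or y",
               class = "metresist_undefined_correlation_error")
  }
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  tibble(n = n, r = r, p_two_sided = p)
}

correlation_tier <- function(p) {
  dplyr::case_when(
    p <= 0.05 ~ "significant",
    p < 0.10 ~ "marginal",
    TRUE ~ "ns"
  )
}

#' Metabolite/feature-versus-phenotype Pearson correlation screen
#'
#' Correlates per-cell-line feature summaries against per-cell-line phenotype
#' values, emitting the full rectangular feature x phenotype (x condition)
#' table with significance tiers (significant: P <= 0.05; marginal:
#' 0.05 < P < 0.10). Accepts either a replicated metabolite panel (features
#' are per-cell-line replicate means of each metabolite, computed separately
#' per condition) or a fold-change table (`condition` reported as `"n/a"`).
#'
#' @param features A metabolite panel (columns `cell_line`, `metabolite`,
#'   `condition`, `replicate`, `concentration`) or a fold-change table
#'   (columns `cell_line`, `metabolite`, `fc`).
#' @param phenotypes Tibble with a `cell_line` column and the phenotype
#'   columns.
#' @param phenotype_names Phenotype columns to screen. Defaults to all numeric
#'   columns of `phenotypes`.
#' @param conditions Conditions to screen when `features` is a panel.
#' @param log10_ic50 Log10-transform phenotype columns whose name contains
#'   `"ic50"` before correlating. Default `FALSE` (raw scale).
#' @returns A tibble: `feature`, `phenotype`, `condition`, `n`, `r`,
#'   `p_two_sided`, `tier`. Features with zero variance are excluded; the
#'   excluded features and reasons are attached as attribute `"excluded"`.
#' @export
correlation_screen <- function(features, phenotypes,
                               phenotype_names = NULL,
                               conditions = c("control", "treated"),
                               log10_ic50 = FALSE) {
  check_columns(phenotypes, "cell_line", "phenotype table")
  if (is.null(phenotype_names)) {
    phenotype_names <- names(phenotypes)[vapply(phenotypes, is.numeric,
                                                logical(1))]
  }
  check_columns(phenotypes, phenotype_names, "phenotype table")
  phen <- phenotypes
  if (log10_ic50) {
    ic_cols <- grep("ic50", phenotype_names, ignore.case = TRUE, value = TRUE)
    phen <- dplyr::mutate(phen, dplyr::across(dplyr::all_of(ic_cols), log10))
  }

  if ("fc" %in% names(features)) {
    check_columns(features, c("cell_line", "metabolite", "fc"),
                  "fold-change table")
    summaries <- features |>
      dplyr::transmute(.data$cell_line, .data$metabolite, condition = "n/a",
                       value = .data$fc)
  } else {
    check_columns(features, c("cell_line", "metabolite", "condition",
                              "replicate", "concentration"),
                  "metabolite panel")
    summaries <- features |>
      dplyr::filter(.data$condition %in% conditions) |>
      dplyr::group_by(.data$cell_line, .data$metabolite, .data$condition) |>
      dplyr::summarise(value = mean(.data$concentration), .groups = "drop")
  }

  shared <- intersect(unique(summaries$cell_line), phen$cell_line)
  if (length(shared) < 3) {
    stop_input(sprintf("only %d shared cell line(s); need >= 3",
                       length(shared)),
               class = "metresist_insufficient_data_error")
  }
  joined <- dplyr::inner_join(summaries, phen, by = "cell_line")

  grid <- joined |>
    dplyr::distinct(.data$metabolite, .data$condition) |>
    tidyr::expand_grid(phenotype = phenotype_names)

  excluded <- list()
  rows <- purrr::pmap(grid, function(metabolite, condition, phenotype) {
    sub <- joined[joined$metabolite == metabolite &
                    joined$condition == condition, ]
    res <- tryCatch(
      pearson_with_p(sub$value, sub[[phenotype]]),
      metresist_undefined_correlation_error = function(e) NULL,
      metresist_insufficient_data_error = function(e) NULL
    )
    if (is.null(res)) {
      excluded[[length(excluded) + 1]] <<- tibble(
        feature = metabolite, phenotype = phenotype, condition = condition,
        reason = "zero variance or too few complete pairs")
      return(NULL)
    }
    dplyr::bind_cols(
      tibble(feature = metabolite, phenotype = phenotype,
             condition = condition),
      res
    )
  })
  out <- dplyr::bind_rows(rows)
  out$tier <- correlation_tier(out$p_two_sided)
  excluded <- dplyr::bind_rows(excluded)
  if (nrow(excluded) > 0) {
    rlang::warn(sprintf("excluded %d feature/phenotype pair(s) with undefined correlation",
                        nrow(excluded)))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Hypergeometric over-representation of metabolite sets
#'
#' One-sided hypergeometric test of whether a set of modulated metabolites
#' over-represents each annotated metabolite set, after intersecting every set
#' with the measured background. Benjamini-Hochberg q-values are computed
#' across the retained sets.
#'
#' @param modulated Character vector of modulated (hit) metabolites; must be a
#'   subset of `background`.
#' @param background Character vector of all measured metabolites.
#' @param sets Named list of metabolite sets.
#' @returns A tibble sorted by P: `set_name`, `k_in_set_hit`, `set_size`,
#'   `n_hits`, `n_background`, `p_hypergeometric`, `q_bh`. Sets with no
#'   overlap with the background are excluded with a warning.
#' @export
msea_ora <- function(modulated, background, sets) {
  background <- unique(background)
  modulated <- unique(modulated)
  if (length(background) == 0) {
    stop_input("empty background", class = "metresist_input_error")
  }
  if (!all(modulated %in% background)) {
    stop_input("modulated metabolites must be a subset of the background",
               class = "metresist_input_error")
  }
  if (length(sets) == 0 || is.null(names(sets))) {
    stop_input("sets must be a non-empty named list",
               class = "metresist_input_error")
  }
  n_bg <- length(background)
  n_hits <- length(modulated)
  trimmed <- purrr::map(sets, ~ intersect(unique(.x), background))
  empty <- names(trimmed)[purrr::map_int(trimmed, length) == 0]
  if (length(empty) > 0) {
    rlang::warn(sprintf("excluded %d set(s) with no background overlap: %s",
                        length(empty), paste(empty, collapse = ", ")))
    trimmed <- trimmed[setdiff(names(trimmed), empty)]
  }
  if (length(trimmed) == 0) return(tibble(
    set_name = character(), k_in_set_hit = integer(), set_size = integer(),
    n_hits = integer(), n_background = integer(),
    p_hypergeometric = double(), q_bh = double()))

  out <- purrr::imap(trimmed, function(members, nm) {
    k <- length(intersect(members, modulated))
    m <- length(members)
    tibble(
      set_name = nm, k_in_set_hit = k, set_size = m, n_hits = n_hits,
      n_background = n_bg,
      p_hypergeometric = phyper(k - 1, n_hits, n_bg - n_hits, m,
                                lower.tail = FALSE)
    )
  }) |>
    dplyr::bind_rows()
  out$q_bh <- p.adjust(out$p_hypergeometric, method = "BH")
  dplyr::arrange(out, .data$p_hypergeometric)
}
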