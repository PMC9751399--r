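# Gene expression associations and continuous-phenotype GSEA.

# Coerce a wide expression tibble (first column gene_symbol) or a matrix to a
# genes x cell-lines numeric matrix.
as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr)) || is.null(colnames(expr))) {
      stop_input("expression matrix needs gene rownames and cell-line colnames",
                 class = "metresist_input_error")
    }
    return(expr)
  }
  check_columns(expr, "gene_symbol", "expression table")
  mat <- as.matrix(expr[setdiff(names(expr), "gene_symbol")])
  rownames(mat) <- expr$gene_symbol
  storage.mode(mat) <- "double"
  mat
}

# Align expression to a named phenotype vector; returns list(mat, phenotype).
align_expression <- function(expr, phenotype) {
  mat <- as_expression_matrix(expr)
  if (is.null(names(phenotype))) {
    stop_input("phenotype must be a named vector (names = cell lines)",
               class = "metresist_input_error")
  }
  phenotype <- phenotype[!is.na(phenotype)]
  shared <- intersect(colnames(mat), names(phenotype))
  if (length(shared) < 3) {
    stop_input(sprintf("only %d shared cell line(s) between expression and phenotype; need >= 3",
                       length(shared)),
               class = "metresist_join_error")
  }
  list(mat = mat[, shared, drop = FALSE], phenotype = phenotype[shared])
}

#' Gene-expression versus phenotype correlation screen
#'
#' Pearson correlation of each gene's expression row against a per-cell-line
#' phenotype (a metabolite level, an IC50, a doubling time), with two-sided
#' t-test P-values and significance tiers as in [correlation_screen()].
#'
#' @param expr Wide expression table (first column `gene_symbol`, one column
#'   per cell line, log2 values) or an equivalent named matrix.
#' @param phenotype Named numeric vector (names = cell lines).
#' @param gene_list Optional character vector restricting the screen.
#' @param phenotype_name Label recorded in the output.
#' @returns A tibble `feature`, `phenotype`, `n`, `r`, `p_two_sided`, `tier`.
#'   Constant (zero-variance) genes are excluded; they are reported in the
#'   attribute `"excluded"` with a reason.
#' @export
gene_phenotype_correlations <- function(expr, phenotype, gene_list = NULL,
                                        phenotype_name = "phenotype") {
  al <- align_expression(expr, phenotype)
  mat <- al$mat
  if (!is.null(gene_list)) {
    keep <- rownames(mat) %in% toupper(gene_list)
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) == 0) {
    stop_input("no genes to screen after restriction",
               class = "metresist_input_error")
  }
  n <- ncol(mat)
  sds <- apply(mat, 1, sd)
  constant <- sds == 0
  excluded <- tibble(feature = rownames(mat)[constant],
                     reason = "constant expression row")
  mat <- mat[!constant, , drop = FALSE]
  if (nrow(excluded) > 0) {
    rlang::warn(sprintf("excluded %d constant gene row(s)", nrow(excluded)))
  }
  r <- as.vector(cor(t(mat), al$phenotype))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- pmax(2 * pt(-abs(t_stat), df = n - 2), .Machine$double.xmin)
  p[abs(r) >= 1 - 1e-15] <- .Machine$double.xmin
  out <- tibble(
    feature = rownames(mat), phenotype = phenotype_name, n = n,
    r = r, p_two_sided = p, tier = correlation_tier(p)
  ) |>
    dplyr::arrange(.data$p_two_sided)
  attr(out, "excluded") <- excluded
  out
}

#' Rank genes by Pearson correlation with a continuous phenotype
#'
#' The ranking metric used for continuous-phenotype GSEA: genes sorted by
#' descending correlation, ties broken by gene symbol so the order is stable
#' and deterministic. Zero-variance genes are dropped (count reported via a
#' message).
#'
#' @inheritParams gene_phenotype_correlations
#' @returns A tibble `gene`, `r`, in ranking order.
#' @export
rank_genes <- function(expr, phenotype) {
  al <- align_expression(expr, phenotype)
  mat <- al$mat
  sds <- apply(mat, 1, sd)
  n_dropped <- sum(sds == 0)
  if (n_dropped > 0) {
    rlang::inform(sprintf("rank_genes: dropped %d zero-variance gene(s)",
                          n_dropped))
    mat <- mat[sds > 0, , drop = FALSE]
  }
  r <- as.vector(cor(t(mat), al$phenotype))
  tibble(gene = rownames(mat), r = r) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$gene)
}

# Weighted Kolmogorov-Smirnov enrichment score from the sorted positions of
# the set's members in the ranked list. Equivalent to the full running sum
# (hits increment by |r|^p normalized, misses decrement by 1/(N - N_hits)),
# but evaluated only at hit boundaries where the extrema occur.
es_from_positions <- function(positions, abs_weights, n_total) {
  k <- length(positions)
  w <- abs_weights[positions]
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep(1 / k, k)
  cw <- cumsum(w)
  miss_dec <- if (k == n_total) 0 else 1 / (n_total - k)
  before <- (positions - seq_len(k)) * miss_dec
  top <- cw - before
  bottom <- c(0, cw[-k]) - before
  hi <- max(top)
  lo <- min(bottom)
  # positive deviation wins a tie; the tolerance keeps the choice stable when
  # the two extrema agree to rounding error
  if (hi + lo >= -1e-12) hi else lo
}

#' Gene set enrichment score (weighted Kolmogorov-Smirnov statistic)
#'
#' Classic GSEA running sum over a ranked gene list: positions holding set
#' members increment the sum by `|r|^p / sum(|r|^p over hits)`, every other
#' position decrements it by `1 / (N - N_hits)`; the enrichment score is the
#' maximum-magnitude deviation from zero (signed; a positive tie wins).
#'
#' @param ranked Tibble from [rank_genes()] (columns `gene`, `r`), already in
#'   ranking order.
#' @param set Character vector of gene symbols.
#' @param weight_p Weighting exponent applied to `|r|`. Default 1.
#' @returns The enrichment score, a number in `[-1, 1]`.
#' @examples
#' ranked <- tibble::tibble(gene = c("A", "B", "C", "D"),
#'                          r = c(0.8, 0.4, -0.4, -0.8))
#' gsea_es(ranked, set = "B")
#' @export
gsea_es <- function(ranked, set, weight_p = 1) {
  check_columns(ranked, c("gene", "r"), "ranked gene list")
  positions <- which(ranked$gene %in% set)
  if (length(positions) == 0) {
    stop_input("no set members found in the ranked list",
               class = "metresist_no_overlap_error")
  }
  es_from_positions(positions, abs(ranked$r)^weight_p, nrow(ranked))
}

#' Full GSEA running sum for plotting
#'
#' @inheritParams gsea_es
#' @returns A tibble `rank`, `gene`, `r`, `hit`, `running_sum`.
#' @export
gsea_running_sum <- function(ranked, set, weight_p = 1) {
  check_columns(ranked, c("gene", "r"), "ranked gene list")
  hit <- ranked$gene %in% set
  if (!any(hit)) {
    stop_input("no set members found in the ranked list",
               class = "metresist_no_overlap_error")
  }
  n <- nrow(ranked)
  k <- sum(hit)
  w <- abs(ranked$r)^weight_p
  sw <- sum(w[hit])
  inc <- if (sw > 0) w * hit / sw else hit / k
  dec <- if (k == n) 0 else (1 - hit) / (n - k)
  tibble(rank = seq_len(n), gene = ranked$gene, r = ranked$r, hit = hit,
         running_sum = cumsum(inc - dec))
}

#' Continuous-phenotype GSEA with gene-set permutation
#'
#' Ranks genes by Pearson correlation with the phenotype ([rank_genes()]),
#' computes each set's enrichment score ([gsea_es()]), and builds a per-set
#' null distribution from `n_perm` random gene sets of the same size drawn
#' from the ranked universe. The normalized enrichment score (NES) divides
#' the ES by the mean magnitude of same-sign null scores; the nominal P is
#' `(1 + #(|null ES| >= |ES|)) / (1 + n_perm)` so it is never zero; the FDR q
#' follows the sign-stratified NES convention (null and observed NES pooled
#' within each sign). Results are reproducible bit-for-bit under a fixed
#' seed.
#'
#' @inheritParams rank_genes
#' @param sets Named list of gene sets (symbol vectors).
#' @param n_perm Number of gene-set permutations. Default 1000; values below
#'   100 trigger a warning.
#' @param weight_p Weighting exponent for [gsea_es()].
#' @param min_size,max_size Matched-size window for eligible sets.
#' @param seed Optional integer seed.
#' @returns A tibble of class `"gsea_result"`, sorted by nominal P:
#'   `set_name`, `n_matched`, `es`, `nes`, `p_nominal`, `fdr_q`,
#'   `significant` (`p_nominal <= 0.05 & fdr_q <= 0.05`).
#' @export
gsea_permutation <- function(expr, phenotype, sets, n_perm = 1000,
                             weight_p = 1, min_size = 15, max_size = 500,
                             seed = NULL) {
  if (n_perm < 100) {
    rlang::warn(sprintf("n_perm = %d is very low; P-values will be coarse",
                        n_perm))
  }
  if (!is.null(seed)) set.seed(seed)
  ranked <- rank_genes(expr, phenotype)
  n <- nrow(ranked)
  absw <- abs(ranked$r)^weight_p
  gene_index <- seq_len(n)

  matched <- purrr::map(sets, ~ which(ranked$gene %in% toupper(.x)))
  sizes <- purrr::map_int(matched, length)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    rlang::inform("gsea_permutation: no sets within the size window")
    empty <- tibble(set_name = character(), n_matched = integer(),
                    es = double(), nes = double(), p_nominal = double(),
                    fdr_q = double(), significant = logical())
    class(empty) <- c("gsea_result", class(empty))
    return(empty)
  }
  matched <- matched[keep]

  per_set <- purrr::imap(matched, function(pos, nm) {
    k <- length(pos)
    es_obs <- es_from_positions(sort(pos), absw, n)
    null_es <- vapply(seq_len(n_perm), function(b) {
      es_from_positions(sort(sample(gene_index, k)), absw, n)
    }, numeric(1))
    pos_mean <- mean(null_es[null_es > 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    if (!is.finite(pos_mean)) pos_mean <- mean(abs(null_es))
    if (!is.finite(neg_mean)) neg_mean <- mean(abs(null_es))
    nes <- if (es_obs >= 0) es_obs / pos_mean else es_obs / neg_mean
    null_nes <- ifelse(null_es >= 0, null_es / pos_mean, null_es / neg_mean)
    p <- (1 + sum(abs(null_es) >= abs(es_obs))) / (1 + n_perm)
    list(row = tibble(set_name = nm, n_matched = k, es = es_obs, nes = nes,
                      p_nominal = p),
         null_nes = null_nes)
  })

  out <- dplyr::bind_rows(purrr::map(per_set, "row"))
  pooled_null <- unlist(purrr::map(per_set, "null_nes"), use.names = FALSE)
  out$fdr_q <- gsea_fdr(out$nes, pooled_null)
  out$significant <- out$p_nominal <= 0.05 & out$fdr_q <= 0.05
  out <- dplyr::arrange(out, .data$p_nominal)
  class(out) <- c("gsea_result", class(out))
  out
}

# Sign-stratified GSEA FDR: for each observed NES, the ratio of the null tail
# fraction to the observed tail fraction within the same sign, clipped to
# [0, 1].
gsea_fdr <- function(obs_nes, null_nes) {
  vapply(obs_nes, function(s) {
    if (s >= 0) {
      null_tail <- mean(null_nes[null_nes >= 0] >= s)
      obs_tail <- mean(obs_nes[obs_nes >= 0] >= s)
    } else {
      null_tail <- mean(null_nes[null_nes < 0] <= s)
      obs_tail <- mean(obs_nes[obs_nes < 0] <= s)
    }
    if (!is.finite(null_tail)) null_tail <- 1
    if (!is.finite(obs_tail) || obs_tail == 0) return(1)
    min(1, null_tail / obs_tail)
  }, numeric(1))
}
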