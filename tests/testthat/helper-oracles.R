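# Independent oracles used to validate the package's own implementations.
# These deliberately use the most direct (brute-force / textbook-formula)
# route, not the package's code paths.

# Exact two-sided signed-rank P by full enumeration of all 2^n sign
# assignments (feasible for n <= ~15).
oracle_signed_rank_p <- function(fc, mu = 1) {
  d <- fc - mu
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  w_obs <- sum(r[d > 0])
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Pearson r and two-sided t-test P from the covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

# GSEA enrichment score by materializing the full running sum.
oracle_gsea_es <- function(r_ranked, hit, weight_p = 1) {
  n <- length(r_ranked)
  k <- sum(hit)
  w <- abs(r_ranked)^weight_p
  sw <- sum(w[hit])
  inc <- if (sw > 0) w * hit / sw else hit / k
  dec <- if (k == n) rep(0, n) else (1 - hit) / (n - k)
  rs <- cumsum(inc - dec)
  hi <- max(rs)
  lo <- min(rs)
  if (hi + lo >= -1e-12) hi else lo   # positive deviation wins an exact tie
}

# Small noise-free metabolite panel with hand-controllable effects.
make_toy_panel <- function(cell_lines = paste0("cl", 1:6),
                           metabolites = c("a", "b", "c"),
                           effects = c(a = 2),
                           n_rep = 3, base = 10) {
  grid <- tidyr::expand_grid(
    cell_line = cell_lines, metabolite = metabolites,
    condition = c("control", "treated"), replicate = seq_len(n_rep)
  )
  eff <- rep(1, length(metabolites))
  names(eff) <- metabolites
  eff[names(effects)] <- effects
  dplyr::mutate(
    grid,
    concentration = base * ifelse(condition == "treated",
                                  eff[metabolite], 1)
  )
}
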