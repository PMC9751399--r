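---
title: "Methods: metabolome-linked drug-resistance screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolome-linked drug-resistance screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metresist)
library(dplyr)
```

`metresist` implements the computational backbone of a common experimental
design in leukemia pharmacology: a panel of cell lines is profiled by
quantitative ^1^H-NMR metabolomics in control and drug-treated conditions,
drug potency (IC50) is measured at two assay horizons, gene expression is
available as a log2 matrix, and candidate drug pairs are screened as
fixed-ratio combinations. The package answers four questions. Which
metabolites does the drug move? Which metabolite levels track resistance?
Does the transcriptome corroborate the metabolite story? And do two drugs
interact beyond Bliss additivity?

This vignette records the statistical models, the numerical choices, and the
design decisions that were genuinely open, in enough detail that a maintainer
can audit every branch.

## Fold-change screening with an exact signed-rank test

For each cell line and metabolite, the treatment effect is summarized as the
fold change `fc = mean(treated replicates) / mean(control replicates)`.
Missing replicates are ignored rather than imputed, and a zero control mean
is a hard error (the ratio is undefined, and silently dropping the entry
would bias the screen).

Whether a metabolite is systematically moved by the drug is tested with a
Wilcoxon signed-rank test of the per-cell-line fold changes against the
hypothetical value 1. The implementation choices, where the test has
variants:

* differences `fc - 1` exactly equal to zero are dropped;
* absolute differences are ranked with **midranks** for ties;
* for `n <= 25` usable values, the two-sided P comes from the **exact** null
  distribution of the positive rank sum over all `2^n` sign assignments.
  The distribution is built by dynamic-programming convolution with ranks
  doubled to integers, so midranks are handled exactly rather than by
  falling back to an approximation (the fallback base R's `wilcox.test`
  takes under ties);
* for `n > 25` a normal approximation with continuity and tie corrections is
  used; at that size the approximation error is far below any decision
  threshold in use (the test suite compares the two regimes at the boundary);
* the two-sided P is `min(1, 2 * min(lower tail, upper tail))`, the same
  convention the exact enumeration implies.

Direction calls (`increased` / `decreased`) require both `P <= alpha` and a
median fold change on the corresponding side of 1. Following the screening
practice this design mirrors, **no multiple-testing correction is applied by
default** — each metabolite is reported marginally; a Benjamini–Hochberg
column can be switched on in the pipeline (`adjust: bh`). At `alpha = 0.05`
about 5% of truly null metabolites are expected to be flagged; the
planted-effect recovery test makes that tolerance explicit.

## Correlation screens

Associations between per-cell-line summaries (metabolite replicate means, or
fold changes) and phenotypes (doubling time in days, IC50 in nM at 48 h and
96 h) use the sample Pearson correlation with the usual two-sided t-test,
`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Pairs with
a missing member are dropped; a zero-variance vector is an explicit
`undefined-correlation` error rather than an `NA`, because in a screen a
silent `NA` row is easily mistaken for "tested, not significant". A perfect
correlation reports the smallest representable positive P rather than zero.

Results carry the three-tier significance labels used in this literature:
significant (`P <= 0.05`), marginal (`0.05 < P < 0.10`), and `ns`.
Correlations are computed on **raw** concentrations and raw IC50s by default;
a `log10_ic50` flag transforms the potency axis first. Both modes exist
because with a dozen cell lines the two conventions can move `r` by
0.05–0.1, and published tables do not always say which was used; the package
refuses to guess and exposes the switch.

## Metabolite-set over-representation

Pathway-level summaries of the modulated metabolites use a one-sided
hypergeometric over-representation test: each annotated set is first
intersected with the measured background (here, the quantified panel), then
`P = P(X >= k)` for `k` modulated members out of a set of size `m`, with
Benjamini–Hochberg q-values across sets. This deliberately replaces
platform-specific enrichment scores with a fully specified, dependency-free
test: the qualitative question ("which pathways are over-represented among
the moved metabolites?") is the same, and every number is reproducible from
the contingency table. Sets with no background overlap are excluded with a
warning, not silently.

## Dose–response summaries

Viability surfaces are tidy tables of live fraction over dose x time x
replicate. Raw signals are normalized against vehicle and death controls,
`(raw - death) / (vehicle - death)`, clipped to [0, 1]; inverted controls
are an error.

**IC50 / LD50.** The primary estimator fits a four-parameter logistic on
log10 dose by bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) with
`top <= 1.05`, `bottom in [-0.05, 0.45]`, slope in [0.05, 20] — bounds wide
enough to absorb noise while keeping the curve physical. The reported value
is the dose where the fitted curve crosses live fraction 0.5 (the median
effect), which matches the screening literature's "LD50" rather than the
4PL's inflection parameter (the two coincide only when `top + bottom = 1`).
Because a start at a perfectly symmetric configuration can make the initial
Jacobian singular, the fitter retries from a short list of nudged starting
points before giving up. On failure the estimator falls back to linear
interpolation of the first downward 0.5 crossing in live fraction versus
log10 dose — the natural axis for the 1:3 serial dilutions these assays use.
When the measured fractions never bracket 0.5, the estimate is **censored**
(`above_max` / `below_min`) instead of erroring: five-point dilution series
frequently miss the midpoint and the information is directional, not absent.
A flat profile at exactly 0.5 is reported as censored too — the crossing
dose is unidentified.

**AUC.** The dose-axis area under the curve at a time slice is the
trapezoidal integral of live fraction against log10 dose, divided by the
log-dose span, giving a dimensionless value in [0, 1] (1 = no kill
anywhere). The normalization makes AUC comparable across panels with
different dose ranges.

**Doubling time** is the reciprocal least-squares slope of log2 cell counts
versus time in days (on replicate means, at least three time points); a
non-positive slope is a `non-growing-culture` error.

Time slices are selected as the nearest measured time, with ties resolved
toward the later point; LD50s default to the final common time point,
matching the 96-hour horizon of the screening assay this mirrors. Whether a
published combination score used a fixed-time LD50 or a time-aggregated
quantity is often ambiguous, which is why the slice is a parameter
(`t`) everywhere rather than a constant.

## Continuous-phenotype GSEA with gene-set permutation

Genes are ranked by Pearson correlation of their expression rows with a
continuous phenotype (a metabolite level or an IC50), descending, with ties
broken alphabetically so the ranking is deterministic. The enrichment score
is the classic weighted Kolmogorov–Smirnov running sum: hits increment by
`|r|^p / sum over hits`, misses decrement by `1 / (N - N_hits)`, and the ES
is the maximum-magnitude signed deviation. `p = 1` (the platform-default
"weighted" statistic) is the default. Two numerical details: the
implementation evaluates the running sum only at hit boundaries (where the
extrema necessarily lie), and an exact tie between the positive and negative
extremum resolves to the positive one, with a `1e-12` tolerance so the
choice does not depend on floating-point summation order. A degenerate set
containing every ranked gene has no misses; its ES is 1 by construction.

The null model is **gene-set permutation** — `n_perm` random same-size sets
drawn from the ranked universe — not phenotype permutation, which is
underpowered at a dozen samples. Per set:

* `NES = ES / mean(|null ES| of the matching sign)`;
* `p_nominal = (1 + #(|null ES| >= |ES|)) / (1 + n_perm)`. Counting by
  magnitude over all permutations keeps the estimator exactly calibrated
  (observed and null ES are exchangeable under the null) and the `+1` keeps
  P strictly positive;
* FDR q follows the sign-stratified convention: within each sign, the
  pooled null NES tail fraction divided by the observed NES tail fraction,
  clipped to [0, 1].

A set is `significant` when `p_nominal <= 0.05` **and** `fdr_q <= 0.05`,
with `n_perm = 1000` by default. Everything is reproducible bit-for-bit
under a fixed seed.

## Bliss synergy scoring of fixed-ratio combinations

A fixed-ratio combination keeps `c_b / c_a = rho` along the dose ray. The
Bliss-independence reference composes **surviving fractions**
multiplicatively: `f_add(c, t) = f_a(c_a, t) * f_b(c_b, t)` (equivalently
`E_add = E_a + E_b - E_a * E_b` on fractions affected — stated explicitly
because composing the wrong complement is the classic implementation error).
Single-agent fractions are evaluated by linear interpolation on log10 dose;
beyond a measured grid the boundary value is carried constant and the point
is flagged `extrapolated`, with a warning.

The synergy score is
`log2(LD50_additive / LD50_combination)`
at a common time slice and on a common reference dose axis (drug A's
concentration by default; "total dose" is available — published combination
LD50s rarely state their axis, so it is a declared parameter here). Positive
scores mean the combination reaches the median effect at lower doses than
additivity predicts. Scores satisfy two exact invariances that the test
suite enforces: multiplying every dose by a constant leaves the score
unchanged, and swapping the drug labels (with `rho -> 1/rho` and the
reference axis adjusted) leaves it unchanged. When either LD50 is censored
the score is censored with a directional bound (e.g. "score >= 0.4" when the
combination out-kills its dose range); bounds that clear the call threshold
still produce a synergy/antagonism call. The call threshold (default 0.25
log2 units, i.e. a 19% dose shift) is a configurable convention, not an
estimate: published reports of "synergy in k of n lines" rarely state their
cutoff.

## The synthetic-data generator

`simulate_panel()` generates the full input bundle with known ground truth,
so every downstream stage is testable without external data. Its defaults
are the study conditions this pipeline is shaped around: 13 cell lines
(6 B-precursor, 7 T-lineage), 70 metabolites, 3 biological replicates per
condition, IC50 ranges of 10.8–101.1 nM (48 h) and 5.5–38.4 nM (96 h),
doubling times of 1–3 days.

* **Concentrations are lognormal.** NMR-quantified metabolite levels are
  positive and right-skewed; the between-cell-line spread is 0.3 on the log
  scale and replicate noise is multiplicative lognormal with mean 1 and CV
  `replicate_cv` (default 0.1 — a free knob, since per-metabolite variance
  structure is rarely published).
* **Treatment effects are multiplicative.** By default 19 metabolites are
  increased (multipliers 1.4–2.2, bracketing the ~2-fold shifts typical of
  strong antifolate responses) and 12 decreased (0.45–0.8). With
  `replicate_cv = 0`, every fold change equals its planted multiplier
  exactly — the noise-free construction several tests rely on.
* **Correlations are planted through shared latent Gaussians.** The
  glutathione-like metabolite's cell-line level and the 96 h IC50 load on a
  common standard-normal factor; the latent correlation is solved in closed
  form (bivariate-lognormal moment inversion) so that the **natural-scale**
  Pearson correlation equals the target (default 0.7) in expectation.
  The same mechanism links doubling time to the 48 h IC50 (default target
  0.83). Replicate-noise attenuation of the observed correlation is below
  0.01 at the default settings and is ignored.
* **One gene set is planted.** Members of `GSH_METABOLISM` (30 genes) load
  on the glutathione latent with correlation 0.7; background sets are random
  draws of 15–40 genes.
* **Viability surfaces are Hill curves**, `f = 1 / (1 + (c / IC50(t))^h)`,
  with IC50(t) decaying geometrically between the 48 h and 96 h anchors
  (only the two endpoints are ever measured; geometric decay is the neutral
  interpolation on a positive scale). Noisy fractions are clipped to [0, 1]
  after multiplication because downstream interpolation assumes fractions.
* **Combinations are additive surfaces evaluated at `c * 2^lambda`**, so the
  true synergy score equals `lambda` by construction and `lambda = 0` is
  exactly additive.

What the generator does **not** emulate: heteroscedastic per-metabolite
noise, batch structure, censored or missing wells, correlated metabolites
within pathways, probe-level expression artifacts, or non-Hill (biphasic)
dose responses. Tests passing on this generator therefore demonstrate that
the estimators recover what they claim under the stated statistical model —
not that real spectra deconvolve cleanly or that real dose responses are
logistic.

## Problem sizes used by the test suite

The suite checks the exact signed-rank distribution against full `2^n`
enumeration for `n <= 12`, the ES against a brute-force running sum for
lists up to 50 genes, GSEA type-I calibration on 500 random sets across five
seeded replicates (`n_perm = 1000`, 800 genes, 20 samples), planted-effect
recovery on a 200-cell-line panel, and synergy recovery over 20 noise seeds.
These sizes give the Monte-Carlo bands quoted in the tests (e.g. the 5%
level held within +/-2 percentage points) while keeping the full suite fast
enough to run on every change.

## Known limitations

* The 4PL fit averages replicates before fitting; replicate-level weighting
  is not implemented.
* Censored synergy scores carry a single directional bound, not an interval;
  bootstrap confidence intervals for the score are future work.
* Loewe, ZIP, HSA and response-surface synergy models are out of scope; the
  score is Bliss-referenced by design.
* The GSEA FDR is the conventional sign-stratified estimator; it is not
  monotone in NES by construction and can be conservative with few sets.
* With 13 cell lines, a planted correlation of 0.7 has a sampling standard
  deviation near 0.15: single-panel correlation estimates are reported as
  observed, and only the large-`n` recovery tests pin them against targets.
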