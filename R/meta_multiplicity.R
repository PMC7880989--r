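## Fixed-effects inverse-variance meta-analysis with Cochran's Q and
## I-squared, plus the multiplicity rules: Bonferroni thresholds
## (alpha / number of tests) and Benjamini-Hochberg step-up q-values.

#' Inverse-variance fixed-effects meta-analysis
#'
#' `w_k = 1/se_k^2`, pooled effect `sum(w theta)/sum(w)`, pooled se
#' `sum(w)^(-1/2)`, `Q = sum w (theta - pooled)^2` with a chi-square test on
#' k-1 df, and `I2 = max(0, (Q - (k-1))/Q)`. A single study passes through
#' unchanged with Q = 0 and I2 undefined (NA). Non-converged estimates are
#' skipped with a warning.
#'
#' @param estimates `data.table` of per-cohort rows (beta, se, optionally
#'   converged, cohort, n_cases, n_controls) sharing one outcome/exposure.
#' @return One-row `data.table`: outcome, exposure, k, beta, se, p, or,
#'   cochran_q, p_q, i2, n_cases, n_controls.
#' @export
fixed_effects_meta <- function(estimates) {
  e <- as.data.table(estimates)
  if (nrow(e) == 0) stopf("fixed_effects_meta: no estimates supplied")
  if ("converged" %in% names(e) && any(!e$converged)) {
    warnf("skipping %d non-converged estimate(s)", sum(!e$converged))
    e <- e[converged == TRUE]
  }
  if (nrow(e) == 0) stopf("fixed_effects_meta: no converged estimates")
  if (any(!is.finite(e$se)) || any(e$se <= 0))
    stopf("fixed_effects_meta: standard errors must be positive and finite")
  w <- 1 / e$se^2
  k <- nrow(e)
  beta <- sum(w * e$beta) / sum(w)
  se <- sum(w)^(-0.5)
  q <- sum(w * (e$beta - beta)^2)
  p_q <- if (k >= 2) pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_
  i2 <- if (k >= 2 && q > 0) max(0, (q - (k - 1)) / q) else
    if (k >= 2) 0 else NA_real_
  data.table(outcome = if ("outcome" %in% names(e)) e$outcome[1] else NA_character_,
             exposure = if ("exposure" %in% names(e)) e$exposure[1] else NA_character_,
             k = k, beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), or = exp(beta),
             cochran_q = q, p_q = p_q, i2 = i2,
             n_cases = if ("n_cases" %in% names(e)) sum(e$n_cases) else NA_integer_,
             n_controls = if ("n_controls" %in% names(e)) sum(e$n_controls) else NA_integer_)
}

#' Meta-analyze per-cohort estimates grouped by outcome and exposure
#'
#' @param estimates Stacked per-cohort association rows.
#' @param by Grouping columns (default outcome, exposure).
#' @return `data.table` with one pooled row per group.
#' @export
meta_by_group <- function(estimates, by = c("outcome", "exposure")) {
  e <- as.data.table(estimates)
  e[, {
    r <- fixed_effects_meta(.SD)
    drop_cols <- intersect(names(r), by)
    if (length(drop_cols)) r[, (drop_cols) := NULL]
    r
  }, by = by][]
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate in (0,1) (default 0.05).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`; callers compare p-values strictly below it.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stopf("m must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  alpha / m
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stopf("p-values must lie in (0,1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Annotate meta results with significance calls
#'
#' @param meta Meta result table (column `p`).
#' @param m Bonferroni denominator (default: number of rows).
#' @param alpha Significance level (default 0.05).
#' @param fdr_q FDR level (default 0.05).
#' @return `meta` with `q`, `significant_bonferroni`, `significant_fdr`,
#'   `heterogeneity_flag` (`p_q < 0.05`) columns.
#' @export
annotate_significance <- function(meta, m = nrow(meta), alpha = 0.05,
                                  fdr_q = 0.05) {
  out <- copy(as.data.table(meta))
  thr <- bonferroni_threshold(alpha, m)
  out[, q := bh_fdr(p)]
  out[, significant_bonferroni := p < thr]
  out[, significant_fdr := q < fdr_q]
  if ("p_q" %in% names(out)) out[, heterogeneity_flag := !is.na(p_q) & p_q < 0.05]
  out[]
}
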