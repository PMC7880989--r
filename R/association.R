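## Per-cohort regression models: covariate-adjusted logistic fits for the
## PRS-by-cancer and per-variant log-additive scans, linear fits for
## secondary phenotypes in cancer-free controls. Inference is Wald
## throughout (two-sided normal p for logistic, two-sided t for linear).

#' Fit one covariate-adjusted association model
#'
#' @param data `data.frame`/`data.table` holding outcome, exposure and
#'   covariates; rows with missing values in any model column are dropped.
#' @param outcome Outcome column (0/1 for logistic, numeric for linear).
#' @param exposure Exposure column (standardized PRS or variant dosage).
#' @param covariates Character vector of covariate columns (categorical ones
#'   enter as factors/indicators).
#' @param family `"logistic"` or `"linear"`.
#' @param cohort Optional cohort label carried into the result.
#' @param exposure_label Optional label (defaults to `exposure`).
#' @param outcome_label Optional label (defaults to `outcome`).
#' @return One-row `data.table`: cohort, outcome, exposure, family, n,
#'   n_cases, n_controls, beta, se, p, or, converged.
#' @export
fit_assoc <- function(data, outcome, exposure, covariates = character(),
                      family = c("logistic", "linear"), cohort = NA_character_,
                      exposure_label = exposure, outcome_label = outcome) {
  family <- match.arg(family)
  d <- as.data.table(data)
  cols <- c(outcome, exposure, covariates)
  miss <- setdiff(cols, names(d))
  if (length(miss)) stopf("model columns absent: %s", paste(miss, collapse = ", "))
  d <- d[complete.cases(d[, ..cols]), ..cols]
  if (nrow(d) < 2) stopf("fewer than 2 complete observations")
  ## single-level factors would break model.matrix; drop them silently
  keep_cov <- vapply(covariates, function(cv) length(unique(d[[cv]])) > 1, logical(1))
  covariates <- covariates[keep_cov]
  x <- d[[exposure]]
  if (length(unique(x)) < 2) stopf("constant exposure '%s'", exposure)
  y <- d[[outcome]]
  n_cases <- n_controls <- NA_integer_
  if (family == "logistic") {
    if (!all(y %in% c(0, 1))) stopf("logistic outcome must be 0/1")
    n_cases <- sum(y == 1); n_controls <- sum(y == 0)
    if (n_cases < 1 || n_controls < 1)
      stopf("need at least one case and one control")
  }
  fml <- as.formula(paste(sprintf("`%s`", outcome), "~",
                          paste(sprintf("`%s`", c(exposure, covariates)),
                                collapse = " + ")))
  ## the exposure is always the first model term: its coefficient is row 2
  if (family == "logistic") {
    fit <- suppressWarnings(glm(fml, data = d, family = binomial(),
                                control = stats::glm.control(epsilon = 1e-12,
                                                             maxit = 100)))
    cf <- summary(fit)$coefficients
    beta <- cf[2L, 1]; se <- cf[2L, 2]
    p <- 2 * pnorm(-abs(beta / se))
    converged <- isTRUE(fit$converged) && is.finite(se) &&
      abs(beta) < 15 && se < 100
  } else {
    fit <- lm(fml, data = d)
    cf <- summary(fit)$coefficients
    beta <- cf[2L, 1]; se <- cf[2L, 2]
    p <- 2 * pt(-abs(beta / se), df = fit$df.residual)
    converged <- is.finite(se)
  }
  data.table(cohort = cohort, outcome = outcome_label,
             exposure = exposure_label, family = family,
             n = nrow(d), n_cases = n_cases, n_controls = n_controls,
             beta = beta, se = se, p = p,
             or = if (family == "logistic") exp(beta) else NA_real_,
             converged = converged)
}

#' Covariate-adjusted logistic association
#' @inheritParams fit_assoc
#' @return One-row `data.table`; see [fit_assoc()].
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = character(),
                         cohort = NA_character_, exposure_label = exposure,
                         outcome_label = outcome) {
  fit_assoc(data, outcome, exposure, covariates, family = "logistic",
            cohort = cohort, exposure_label = exposure_label,
            outcome_label = outcome_label)
}

#' Covariate-adjusted linear association (two-sided t inference)
#' @inheritParams fit_assoc
#' @return One-row `data.table`; see [fit_assoc()].
#' @export
fit_linear <- function(data, outcome, exposure, covariates = character(),
                       cohort = NA_character_, exposure_label = exposure,
                       outcome_label = outcome) {
  fit_assoc(data, outcome, exposure, covariates, family = "linear",
            cohort = cohort, exposure_label = exposure_label,
            outcome_label = outcome_label)
}

default_covariates <- function(samples, sex_restricted = FALSE) {
  cov <- c("age", paste0("PC", 1:10), "batch")
  if (!sex_restricted) cov <- c(cov, "sex")
  intersect(cov, names(samples))
}

assoc_frame <- function(samples, assignment, exposure_values, exposure_name) {
  s <- as.data.table(samples)
  d <- s[sample_id %in% c(assignment$cases, assignment$controls)]
  d[, .case := as.integer(sample_id %in% assignment$cases)]
  d[, (exposure_name) := exposure_values[sample_id]]
  d
}

#' Scan every PRS against every cancer outcome in one cohort
#'
#' One logistic fit per (PRS, outcome) with the standard covariates (age,
#' PCs 1-10, genotyping batch, and sex except for sex-specific outcomes).
#'
#' @param z_scores Named list site -> named standardized-score vector.
#' @param assignments Named list site -> `case_control`.
#' @param samples QC-passed sample table.
#' @param sex_specific Named site -> "F"/"M" map.
#' @param cohort Cohort label.
#' @return `data.table` of association rows (exposure `prs_<site>`).
#' @export
prs_scan <- function(z_scores, assignments, samples, sex_specific = NULL,
                     cohort = NA_character_) {
  rows <- list()
  for (site_prs in names(z_scores)) {
    for (site_out in names(assignments)) {
      a <- assignments[[site_out]]
      sex_res <- !is.null(sex_specific) && !is.na(sex_specific[site_out])
      d <- assoc_frame(samples, a, z_scores[[site_prs]], "z")
      rows[[length(rows) + 1L]] <- tryCatch(
        fit_logistic(d, ".case", "z",
                     default_covariates(d, sex_restricted = sex_res),
                     cohort = cohort,
                     exposure_label = paste0("prs_", site_prs),
                     outcome_label = site_out),
        error = function(e) NULL)
    }
  }
  rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

#' Per-variant log-additive scan across cancer outcomes
#'
#' One logistic fit per (PRS variant, outcome). A variant contributing to
#' several PRS is fitted once per origin but flagged `duplicate` after its
#' first occurrence, so unique-variant counts are recoverable.
#'
#' @param prs_defs Named list of PRS definitions.
#' @param dosages Dosage matrix.
#' @param assignments Named list site -> `case_control`.
#' @param samples QC-passed sample table.
#' @param sex_specific Named site -> "F"/"M" map.
#' @param cohort Cohort label.
#' @return `data.table` of association rows plus origin, variant_id,
#'   duplicate.
#' @export
variant_scan <- function(prs_defs, dosages, assignments, samples,
                         sex_specific = NULL, cohort = NA_character_) {
  rows <- list(); seen <- character()
  for (origin in names(prs_defs)) {
    def <- prs_defs[[origin]]
    for (i in seq_len(nrow(def))) {
      vid <- def$variant_id[i]
      dose <- dosages[, vid]
      if (isTRUE(def$flip_dosage[i])) dose <- 2 - dose
      names(dose) <- rownames(dosages)
      for (site_out in names(assignments)) {
        a <- assignments[[site_out]]
        sex_res <- !is.null(sex_specific) && !is.na(sex_specific[site_out])
        d <- assoc_frame(samples, a, dose, "dose")
        est <- tryCatch(
          fit_logistic(d, ".case", "dose",
                       default_covariates(d, sex_restricted = sex_res),
                       cohort = cohort, exposure_label = vid,
                       outcome_label = site_out),
          error = function(e) NULL)
        if (is.null(est)) next
        key <- paste(vid, site_out, sep = "|")
        est[, `:=`(origin = origin, variant_id = vid,
                   duplicate = key %in% seen)]
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- est
      }
    }
  }
  rbindlist(rows)
}

#' PRS associations with secondary phenotypes in cancer-free controls
#'
#' Linear models for quantitative traits, logistic for binary ones
#' (ever/never smoking), restricted to samples that are controls for every
#' cancer (no diagnosis, self-report or cancer death cause), with
#' trait-specific covariates appended to the standard set.
#'
#' @param z_scores Named list site -> standardized-score vector.
#' @param samples Prepared sample table (controls only).
#' @param traits Character vector of trait columns, or named list
#'   trait -> extra covariate columns.
#' @param binary_traits Traits fitted by logistic regression.
#' @param cohort Cohort label.
#' @return `data.table` of association rows.
#' @export
secondary_scan <- function(z_scores, samples, traits,
                           binary_traits = character(),
                           cohort = NA_character_) {
  extra <- if (is.list(traits)) traits else
    setNames(rep(list(character()), length(traits)), traits)
  rows <- list()
  s <- as.data.table(samples)
  for (site in names(z_scores)) {
    s2 <- copy(s)
    s2[, z := z_scores[[site]][sample_id]]
    for (tr in names(extra)) {
      cov <- c(default_covariates(s2), extra[[tr]])
      fam <- if (tr %in% binary_traits) fit_logistic else fit_linear
      rows[[length(rows) + 1L]] <- tryCatch(
        fam(s2, tr, "z", cov, cohort = cohort,
            exposure_label = paste0("prs_", site), outcome_label = tr),
        error = function(e) NULL)
    }
  }
  rbindlist(rows[!vapply(rows, is.null, logical(1))])
}
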