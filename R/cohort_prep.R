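## Sample QC and phenotype derivation: call-rate / heterozygosity / PC
## outlier removal, per-cancer case-control assignment under the
## first-primary rule, incident/prevalent splits, and secondary-trait
## preparation (log transforms, waist-hip ratio, reportable-range censoring).

#' Sample-level quality control
#'
#' Removes samples with call rate below `call_rate_min`, heterozygosity more
#' than `z_max` within-cohort standard deviations from the mean, or PC1/PC2
#' more than `z_max` standard deviations from the mean. Z-scores are
#' computed within the cohort on the QC-input samples.
#'
#' @param samples `data.table` with sample_id, call_rate, het, PC1, PC2.
#' @param call_rate_min Minimum call rate (default 0.97).
#' @param z_max Outlier threshold in SD units (default 5).
#' @param missing_metric `"drop"` or `"keep"`: fate of samples with a missing
#'   QC metric.
#' @return List: `kept` (samples), `removed` (sample_id, reason; multiple
#'   reasons joined with `;`).
#' @export
sample_qc <- function(samples, call_rate_min = 0.97, z_max = 5,
                      missing_metric = c("drop", "keep")) {
  missing_metric <- match.arg(missing_metric)
  s <- as.data.table(samples)
  zs <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  het_z <- zs(s$het); pc1_z <- zs(s$PC1); pc2_z <- zs(s$PC2)
  reasons <- vector("list", nrow(s))
  add <- function(idx, why) for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  add(!is.na(s$call_rate) & s$call_rate < call_rate_min, "low_call_rate")
  add(!is.na(het_z) & abs(het_z) > z_max, "heterozygosity_outlier")
  add(!is.na(pc1_z) & abs(pc1_z) > z_max, "pc1_outlier")
  add(!is.na(pc2_z) & abs(pc2_z) > z_max, "pc2_outlier")
  any_na <- is.na(s$call_rate) | is.na(het_z) | is.na(pc1_z) | is.na(pc2_z)
  if (missing_metric == "drop") add(any_na, "missing_qc_metric")
  drop <- vapply(reasons, function(r) length(r) > 0, logical(1))
  list(kept = s[!drop],
       removed = data.table(sample_id = s$sample_id[drop],
                            reason = vapply(reasons[drop], paste,
                                            character(1), collapse = ";")))
}

#' Assign cases and controls for one cancer type
#'
#' Cases are samples whose earliest-dated primary diagnosis includes the
#' cancer; two primaries on the same earliest date make the sample a case
#' for each tied site. Controls have no registry diagnosis of any cancer, no
#' self-reported cancer history and no cancer-coded cause of death.
#' Sex-specific cancers restrict both sets to the relevant sex. The
#' `incident` subset keeps cases diagnosed strictly after the specimen
#' collection date; `prevalent` keeps those on or before it (a same-date
#' diagnosis counts as prevalent — a fixed convention).
#'
#' @param samples QC-passed sample table (sample_id, sex,
#'   self_report_cancer, death_cause_cancer).
#' @param diagnoses Long table (sample_id, site_code, date).
#' @param site Cancer site code to assign.
#' @param sex_specific Named character vector site -> "F"/"M" for
#'   sex-specific cancers; others unrestricted.
#' @param subset `"all"`, `"incident"` or `"prevalent"`.
#' @param specimen_date Collection `Date` (scalar, or named per sample);
#'   required for incident/prevalent subsets.
#' @param valid_sites Site codes accepted; defaults to those present in
#'   `diagnoses`.
#' @return List of class `case_control`: site, subset, `cases`, `controls`
#'   (character sample ids).
#' @export
assign_case_control <- function(samples, diagnoses, site,
                                sex_specific = NULL,
                                subset = c("all", "incident", "prevalent"),
                                specimen_date = NULL,
                                valid_sites = NULL) {
  subset <- match.arg(subset)
  s <- as.data.table(samples); d <- as.data.table(diagnoses)
  valid_sites <- valid_sites %||% unique(d$site_code)
  if (!site %in% valid_sites)
    stopf("unknown site code '%s'; valid codes: %s", site,
          paste(sort(valid_sites), collapse = ", "))
  d <- d[sample_id %in% s$sample_id]
  d[, .first_date := min(date), by = sample_id]
  first <- d[date == .first_date]  # all same-date ties kept
  case_rows <- first[site_code == site]
  if (subset != "all") {
    if (is.null(specimen_date)) stopf("specimen_date required for subset '%s'", subset)
    spec <- if (length(specimen_date) == 1L)
      rep(as.Date(specimen_date), nrow(case_rows))
    else as.Date(specimen_date[case_rows$sample_id])
    case_rows <- if (subset == "incident") case_rows[case_rows$date > spec]
    else case_rows[case_rows$date <= spec]
  }
  cases <- unique(case_rows$sample_id)
  diagnosed <- unique(d$sample_id)
  ctrl <- s[!sample_id %in% diagnosed &
              !isTRUE_v(self_report_cancer) & !isTRUE_v(death_cause_cancer)]
  req_sex <- if (!is.null(sex_specific)) sex_specific[site] else NA_character_
  if (!is.na(req_sex)) {
    ctrl <- ctrl[sex == req_sex]
    cases <- intersect(cases, s[sex == req_sex, sample_id])
  }
  structure(list(site = site, subset = subset, cases = cases,
                 controls = ctrl$sample_id),
            class = "case_control")
}

isTRUE_v <- function(x) !is.na(x) & x

#' Prepare secondary phenotypes for modeling
#'
#' Natural-log transforms the configured biomarkers (non-positive values set
#' missing and logged), derives waist-to-hip ratio, and censors values
#' outside the reportable range to missing.
#'
#' @param samples Sample table.
#' @param log_traits Columns to replace by their natural log (default
#'   `"crp"`, plus `"hba1c"`, `"igf1"` when present).
#' @param ranges Optional named list trait -> c(lo, hi); values outside are
#'   set missing.
#' @return List: `samples` (transformed; `whr` added when waist/hip
#'   present), `log` (sample_id, trait, action).
#' @export
prepare_secondary_phenotypes <- function(samples,
                                         log_traits = c("crp", "hba1c", "igf1"),
                                         ranges = NULL) {
  s <- copy(as.data.table(samples))
  log_rows <- list()
  ## reportable-range censoring applies to the raw measurements, before any
  ## transformation
  for (tr in names(ranges)) {
    if (!tr %in% names(s)) next
    lo <- ranges[[tr]][1]; hi <- ranges[[tr]][2]
    bad <- which(!is.na(s[[tr]]) & (s[[tr]] < lo | s[[tr]] > hi))
    if (length(bad)) {
      log_rows[[length(log_rows) + 1L]] <- data.table(
        sample_id = s$sample_id[bad], trait = tr, action = "out_of_range_set_missing")
      set(s, bad, tr, NA_real_)
    }
  }
  for (tr in intersect(log_traits, names(s))) {
    bad <- which(!is.na(s[[tr]]) & s[[tr]] <= 0)
    if (length(bad)) {
      log_rows[[length(log_rows) + 1L]] <- data.table(
        sample_id = s$sample_id[bad], trait = tr, action = "nonpositive_set_missing")
      set(s, bad, tr, NA_real_)
    }
    set(s, NULL, tr, log(s[[tr]]))
  }
  if (all(c("waist", "hip") %in% names(s))) s[, whr := waist / hip]
  list(samples = s[],
       log = if (length(log_rows)) rbindlist(log_rows) else
         data.table(sample_id = character(), trait = character(),
                    action = character()))
}
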