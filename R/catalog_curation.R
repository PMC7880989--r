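## Literature-catalog curation: one usable association per
## (variant, phenotype/sub-phenotype, ancestry group), then eligibility
## filters (autosomal, >=70% European ancestry, genome-wide significant,
## effect estimate and effect allele known).

#' Coerce a raw association table to the catalog schema
#'
#' Validates required columns, normalizes the optional ones, and attaches a
#' log-scale weight column: odds ratios are log-transformed at parse time,
#' beta-type effects are taken as already log-scale.
#'
#' @param x data.frame/data.table with columns study_id, phenotype, rsid,
#'   chrom, pos, effect_allele, effect, effect_type ("OR" or "beta"),
#'   p_value; optional subphenotype, ancestry_label, ancestry_eur_fraction,
#'   other_allele, imputation_info, record_id.
#' @return `data.table` with a `key` and `log_or` column added.
#' @export
as_catalog <- function(x) {
  x <- as.data.table(x)
  need <- c("study_id", "phenotype", "rsid", "chrom", "pos",
            "effect_allele", "effect", "effect_type", "p_value")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("catalog lacks columns: %s", paste(miss, collapse = ", "))
  if (!"record_id" %in% names(x)) x[, record_id := sprintf("rec%04d", .I)]
  if (!"subphenotype" %in% names(x)) x[, subphenotype := NA_character_]
  if (!"ancestry_label" %in% names(x)) x[, ancestry_label := "EUR"]
  if (!"ancestry_eur_fraction" %in% names(x)) x[, ancestry_eur_fraction := 1.0]
  if (!"other_allele" %in% names(x)) x[, other_allele := NA_character_]
  if (!"imputation_info" %in% names(x)) x[, imputation_info := NA_real_]
  if (any(!is.na(x$p_value) & (x$p_value <= 0 | x$p_value > 1)))
    stopf("p_value must lie in (0, 1]")
  bad <- setdiff(unique(x$effect_type), c("OR", "beta"))
  if (length(bad)) stopf("unknown effect_type: %s", paste(bad, collapse = ", "))
  x[, chrom := as.character(chrom)]
  x[, log_or := ifelse(effect_type == "OR", log(effect), effect)]
  x[, key := catalog_key(rsid, phenotype, subphenotype, ancestry_label)]
  x[]
}

#' Deduplicate associations to one record per key
#'
#' Key is (variant, phenotype/sub-phenotype, ancestry group). Among the
#' candidates for a key, records with a known effect allele and effect
#' estimate beat those without; within that class the smallest p value wins,
#' ties broken by larger imputation score, then lexicographic study id
#' (a documented convention — the source procedure is silent on ties).
#'
#' @param records Catalog `data.table` from [as_catalog()].
#' @return Deduplicated catalog, one row per key.
#' @export
dedupe_associations <- function(records) {
  if (nrow(records) == 0) return(records)
  r <- copy(records)
  r[, has_estimate := !is.na(log_or) & is.finite(log_or) &
      !is.na(effect_allele) & nzchar(effect_allele)]
  r[, info_rank := fifelse(is.na(imputation_info), -Inf, imputation_info)]
  setorder(r, key, -has_estimate, p_value, -info_rank, study_id)
  out <- r[, .SD[1], by = key]
  out[, c("has_estimate", "info_rank") := NULL]
  setorder(out, record_id)
  out[]
}

#' Apply catalog eligibility filters
#'
#' Retains autosomal records (chrom 1-22) from populations of at least 70%
#' European ancestry, genome-wide significant (p <= 5e-8), with a reported
#' effect estimate and a determinable effect allele. Each exclusion is
#' logged with its reason; a record failing several filters is logged under
#' the first reason in the order above.
#'
#' @param records Deduplicated catalog.
#' @param p_max Genome-wide significance threshold (default `5e-8`).
#' @param eur_min Minimum European-ancestry fraction (default `0.70`).
#' @return List: `kept` (catalog rows), `excluded`
#'   (record_id, key, reason).
#' @export
filter_catalog <- function(records, p_max = 5e-8, eur_min = 0.70) {
  if (nrow(records) == 0)
    return(list(kept = records,
                excluded = as.data.table(list(record_id = character(),
                                              key = character(),
                                              reason = character()))))
  r <- copy(records)
  reason <- rep(NA_character_, nrow(r))
  autosomal <- r$chrom %in% as.character(1:22)
  reason[!autosomal] <- "non-autosomal"
  low_anc <- is.na(reason) & r$ancestry_eur_fraction < eur_min
  reason[low_anc] <- "ancestry_below_min"
  weak <- is.na(reason) & r$p_value > p_max
  reason[weak] <- "not_genomewide_significant"
  no_eff <- is.na(reason) & (!is.finite(r$log_or))
  reason[no_eff] <- "missing_effect_estimate"
  no_ea <- is.na(reason) & (is.na(r$effect_allele) | !nzchar(r$effect_allele))
  reason[no_ea] <- "undetermined_effect_allele"
  keep <- is.na(reason)
  list(kept = r[keep],
       excluded = as.data.table(list(record_id = r$record_id[!keep],
                                     key = r$key[!keep],
                                     reason = reason[!keep])))
}

#' Curate a raw catalog: dedupe then filter
#'
#' @inheritParams filter_catalog
#' @return As [filter_catalog()], plus `n_input` and per-stage counts.
#' @export
curate_catalog <- function(records, p_max = 5e-8, eur_min = 0.70) {
  records <- as_catalog(records)
  dd <- dedupe_associations(records)
  dropped_dupes <- records[!record_id %in% dd$record_id,
                           .(record_id, key, reason = "duplicate_association")]
  fl <- filter_catalog(dd, p_max = p_max, eur_min = eur_min)
  list(kept = fl$kept, excluded = rbind(dropped_dupes, fl$excluded),
       n_input = nrow(records))
}
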