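## Harmonization: match each curated catalog record to the cohort genotype
## panel (directly, by position, or through an LD proxy with r2 >= 0.8),
## reconcile allele coding (dosage complement and strand flips), and apply
## the frequency filters (biallelic, MAF >= 0.01, cohort-vs-reference MAF
## discordance <= 0.10, A/T-C/G exclusion at MAF >= 0.45).

#' Match a catalog record to the panel directly or through a proxy
#'
#' Resolution order: variant id, then (chrom, pos), then the best available
#' proxy with `r2 >= r2_min` within `window` bp on the same chromosome
#' (highest r2; ties broken by nearest bp, then lexicographic id).
#'
#' @param record One catalog row (list or single-row data.table).
#' @param panel Variant manifest (variant_id, chrom, pos, ref, alt).
#' @param ld Optional LD table (var1, var2, r2), symmetric by convention.
#' @param r2_min Minimum proxy r2 (default 0.8).
#' @param window Proxy search window in bp (default 5e5).
#' @return List: `matched` (logical); on success `panel_id`, `matched_via`
#'   ("direct" | "position" | "proxy"), `proxy_r2`; on failure `reason`.
#' @export
match_or_proxy <- function(record, panel, ld = NULL, r2_min = 0.8,
                           window = 5e5) {
  rec <- as.list(record)
  panel <- as.data.table(panel)
  hit <- which(panel$variant_id == rec$rsid)
  if (length(hit) == 1L)
    return(list(matched = TRUE, panel_id = panel$variant_id[hit],
                matched_via = "direct", proxy_r2 = NA_real_))
  hit <- which(panel$chrom == as.character(rec$chrom) & panel$pos == rec$pos)
  if (length(hit) >= 1L)
    return(list(matched = TRUE, panel_id = panel$variant_id[hit[1]],
                matched_via = "position", proxy_r2 = NA_real_))
  if (is.null(ld) || nrow(ld) == 0)
    return(list(matched = FALSE, reason = "no LD information"))
  cand <- rbind(
    data.table(id = ld$var2[ld$var1 == rec$rsid], r2 = ld$r2[ld$var1 == rec$rsid]),
    data.table(id = ld$var1[ld$var2 == rec$rsid], r2 = ld$r2[ld$var2 == rec$rsid]))
  cand <- cand[r2 >= r2_min]
  cand <- merge(cand, panel[, .(id = variant_id, chrom, pos)], by = "id")
  cand <- cand[chrom == as.character(rec$chrom) & abs(pos - rec$pos) <= window]
  if (nrow(cand) == 0)
    return(list(matched = FALSE, reason = "no proxy at r2 threshold"))
  cand[, dist := abs(pos - rec$pos)]
  setorder(cand, -r2, dist, id)
  list(matched = TRUE, panel_id = cand$id[1], matched_via = "proxy",
       proxy_r2 = cand$r2[1])
}

#' Reconcile catalog alleles with the counted panel allele
#'
#' The panel counts the alt allele. If the catalog effect allele equals alt,
#' dosages are used as-is; if it equals ref, the contribution is computed on
#' the complemented dosage 2-d (equivalent to negating the weight up to a
#' constant; standardized scores are identical). If the alleles only match
#' after strand complement (A<->T, C<->G base-wise), the record is flagged
#' strand-flipped and re-resolved the same way. Strand-ambiguous pairs
#' (A/T or C/G) are dropped when MAF >= `ambiguous_maf_max`, since the
#' strand — and hence the effect allele — cannot be determined.
#'
#' @param record Catalog row (needs effect_allele, other_allele).
#' @param panel_row Panel row for the matched variant (ref, alt).
#' @param cohort_maf Cohort minor allele frequency of the matched variant.
#' @param ambiguous_maf_max Drop threshold for ambiguous pairs (default 0.45).
#' @param is_proxy Set for proxy matches: lead alleles cannot be reconciled
#'   against a different variant, so the counted allele is taken from the LD
#'   source convention (panel alt) unchanged.
#' @return List: `ok`; on success `flip_dosage`, `strand_flipped`;
#'   on failure `reason`.
#' @export
harmonize_alleles <- function(record, panel_row, cohort_maf,
                              ambiguous_maf_max = 0.45, is_proxy = FALSE) {
  ref <- toupper(panel_row$ref); alt <- toupper(panel_row$alt)
  panel_ambiguous <- is_ambiguous_pair(ref, alt)
  if (panel_ambiguous && cohort_maf >= ambiguous_maf_max)
    return(list(ok = FALSE, reason = "ambiguous_alleles_high_maf"))
  if (is_proxy)
    return(list(ok = TRUE, flip_dosage = FALSE, strand_flipped = FALSE))
  ea <- toupper(as.character(record$effect_allele))
  oa <- toupper(as.character(record$other_allele %||% NA_character_))
  if (!is.na(ea) && is_ambiguous_pair(ea, oa) && cohort_maf >= ambiguous_maf_max)
    return(list(ok = FALSE, reason = "ambiguous_alleles_high_maf"))
  same_pair <- function(a, b) (is.na(oa) && (a == ea || b == ea)) ||
    (!is.na(oa) && ((a == ea && b == oa) || (a == oa && b == ea)))
  if (same_pair(alt, ref)) {
    flip <- !(ea == alt)
    return(list(ok = TRUE, flip_dosage = flip, strand_flipped = FALSE))
  }
  cea <- complement_allele(ea); coa <- if (is.na(oa)) oa else complement_allele(oa)
  ea <- cea; oa <- coa
  if (same_pair(alt, ref)) {
    flip <- !(ea == alt)
    return(list(ok = TRUE, flip_dosage = flip, strand_flipped = TRUE))
  }
  list(ok = FALSE, reason = "allele_mismatch")
}

#' Apply MAF and reference-concordance filters to a matched variant
#'
#' Drops multi-allelic sites, cohort MAF < `maf_min`, variants absent from
#' the reference frequency table, and |cohort MAF - reference MAF| >
#' `maf_diff_max`. With no reference table the concordance and presence
#' checks are skipped with a warning.
#'
#' @param panel_row Panel row (variant_id, ref, alt).
#' @param cohort_maf Cohort minor allele frequency.
#' @param ref_freqs Optional table (variant_id, ref_alt_freq).
#' @param maf_min Minimum MAF (default 0.01).
#' @param maf_diff_max Maximum |cohort - reference| MAF difference (0.10).
#' @param warn_no_ref Emit the skip warning (default TRUE).
#' @return List: `ok`, `ref_maf`; on failure `reason`.
#' @export
apply_frequency_filters <- function(panel_row, cohort_maf, ref_freqs = NULL,
                                    maf_min = 0.01, maf_diff_max = 0.10,
                                    warn_no_ref = TRUE) {
  if (grepl(",", panel_row$alt, fixed = TRUE))
    return(list(ok = FALSE, reason = "not_biallelic"))
  if (cohort_maf < maf_min)
    return(list(ok = FALSE, reason = "maf_below_min"))
  if (is.null(ref_freqs)) {
    if (warn_no_ref)
      warnf("no reference frequencies supplied; MAF-concordance filter skipped")
    return(list(ok = TRUE, ref_maf = NA_real_))
  }
  i <- match(panel_row$variant_id, ref_freqs$variant_id)
  if (is.na(i))
    return(list(ok = FALSE, reason = "absent_from_reference"))
  ref_maf <- minor_af(ref_freqs$ref_alt_freq[i])
  if (abs(cohort_maf - ref_maf) > maf_diff_max)
    return(list(ok = FALSE, reason = "maf_discordant_with_reference"))
  list(ok = TRUE, ref_maf = ref_maf)
}

#' Harmonize a curated catalog against a cohort panel
#'
#' Runs matching, allele reconciliation and frequency filters for every
#' record; every record maps to exactly one outcome (harmonized or dropped
#' with a reason), so counts conserve. Cohort allele frequency is mean
#' dosage / 2 on the supplied (QC-passed) samples; missing dosages are
#' ignored for the frequency and mean-imputed downstream by the scorer.
#'
#' @param records Curated catalog (`kept` from [curate_catalog()]).
#' @param panel Variant manifest of the cohort.
#' @param dosages Dosage matrix (QC-passed samples x panel variants).
#' @param ld Optional LD table for proxy search (var1, var2, r2).
#' @param ref_freqs Optional reference frequency table.
#' @param r2_min,window,ambiguous_maf_max,maf_min,maf_diff_max Thresholds;
#'   see the per-step functions.
#' @return List: `variants` — one row per harmonized record (record_id, key,
#'   rsid, phenotype, subphenotype, panel_id, matched_via, proxy_r2,
#'   flip_dosage, strand_flipped, cohort_maf, ref_maf, info, p_value,
#'   weight); `report` — one row per input record (record_id, rsid, outcome,
#'   reason, matched_via).
#' @export
harmonize_catalog <- function(records, panel, dosages, ld = NULL,
                              ref_freqs = NULL, r2_min = 0.8, window = 5e5,
                              ambiguous_maf_max = 0.45, maf_min = 0.01,
                              maf_diff_max = 0.10) {
  records <- as.data.table(records)
  panel <- as.data.table(panel)
  afreq <- colMeans(dosages, na.rm = TRUE) / 2
  out <- vector("list", nrow(records))
  rep_rows <- vector("list", nrow(records))
  warned_ref <- FALSE
  for (i in seq_len(nrow(records))) {
    rec <- records[i]
    note <- function(outcome, reason = NA_character_, via = NA_character_) {
      rep_rows[[i]] <<- data.table(record_id = rec$record_id, rsid = rec$rsid,
                                   outcome = outcome, reason = reason,
                                   matched_via = via)
    }
    m <- match_or_proxy(rec, panel, ld, r2_min = r2_min, window = window)
    if (!m$matched) { note("dropped", m$reason); next }
    prow <- panel[variant_id == m$panel_id]
    maf <- minor_af(afreq[[m$panel_id]])
    al <- harmonize_alleles(rec, prow, maf,
                            ambiguous_maf_max = ambiguous_maf_max,
                            is_proxy = m$matched_via == "proxy")
    if (!al$ok) { note("dropped", al$reason, m$matched_via); next }
    fr <- apply_frequency_filters(prow, maf, ref_freqs, maf_min = maf_min,
                                  maf_diff_max = maf_diff_max,
                                  warn_no_ref = !warned_ref)
    if (is.null(ref_freqs)) warned_ref <- TRUE
    if (!fr$ok) { note("dropped", fr$reason, m$matched_via); next }
    note("harmonized", via = m$matched_via)
    out[[i]] <- as.data.table(list(
      record_id = rec$record_id, key = rec$key, rsid = rec$rsid,
      phenotype = rec$phenotype, subphenotype = rec$subphenotype,
      panel_id = m$panel_id, matched_via = m$matched_via,
      proxy_r2 = m$proxy_r2, flip_dosage = al$flip_dosage,
      strand_flipped = al$strand_flipped, cohort_maf = maf,
      ref_maf = fr$ref_maf, info = rec$imputation_info,
      p_value = rec$p_value, weight = rec$log_or))
  }
  variants <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(variants) == 0)
    variants <- as.data.table(list(
      record_id = character(), key = character(), rsid = character(),
      phenotype = character(), subphenotype = character(),
      panel_id = character(), matched_via = character(),
      proxy_r2 = numeric(), flip_dosage = logical(),
      strand_flipped = logical(), cohort_maf = numeric(),
      ref_maf = numeric(), info = numeric(), p_value = numeric(),
      weight = numeric()))
  list(variants = variants, report = rbindlist(rep_rows))
}
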