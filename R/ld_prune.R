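## Pairwise dosage LD and greedy priority pruning: keep, per cancer, an
## independent (r2 < 0.3) variant set, preferring the broadest phenotype,
## then smallest p, then highest imputation score.

#' Squared Pearson correlation of two dosage vectors
#'
#' Computed over shared non-missing samples. Undefined (NA) when fewer than
#' two shared samples remain or either vector is constant.
#'
#' @param x,y Numeric dosage vectors of equal length.
#' @return r-squared in `[0,1]`, or `NA_real_` when undefined.
#' @export
pairwise_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' In-cohort LD matrix for a set of panel variants
#'
#' @param dosages Dosage matrix (samples x variants).
#' @param ids Variant ids (columns) to include.
#' @return Symmetric r-squared matrix with unit diagonal; `NA` where
#'   undefined.
#' @export
ld_from_dosages <- function(dosages, ids = colnames(dosages)) {
  d <- dosages[, ids, drop = FALSE]
  sds <- apply(d, 2, sd, na.rm = TRUE)
  r2 <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
  r2[sds == 0, ] <- NA; r2[, sds == 0] <- NA
  diag(r2) <- 1
  r2
}

ld_lookup <- function(ld, i, j, chrom_i = NA, chrom_j = NA) {
  if (!is.na(chrom_i) && !is.na(chrom_j) && chrom_i != chrom_j) return(0)
  if (is.matrix(ld)) {
    if (i %in% rownames(ld) && j %in% colnames(ld)) return(ld[i, j])
    return(NA_real_)
  }
  hit <- ld[(ld$var1 == i & ld$var2 == j) | (ld$var1 == j & ld$var2 == i), ]
  if (nrow(hit)) hit$r2[1] else NA_real_
}

#' Greedy priority pruning of candidate variants
#'
#' Candidates are processed in priority order — broadest phenotype first
#' (ascending `breadth`, 0 = broadest), then ascending p value, descending
#' imputation score, lexicographic id — and accepted iff their r2 against
#' every previously accepted variant is below `r2_max`. Pairs on different
#' chromosomes are assumed independent without lookup; pairs with no LD
#' information are treated as independent and noted in the report.
#'
#' @param candidates `data.table` with variant_id, p, info, and optionally
#'   breadth (default 0) and chrom.
#' @param ld LD source: symmetric r2 matrix (dimnames = variant ids) or a
#'   long table (var1, var2, r2).
#' @param r2_max Independence threshold (default 0.3, exclusive).
#' @return List: `kept` (variant ids in priority order), `report`
#'   (variant_id, kept, removed_by, note).
#' @export
priority_prune <- function(candidates, ld, r2_max = 0.3) {
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0) {
    warnf("priority_prune: empty candidate list")
    return(list(kept = character(),
                report = data.table(variant_id = character(), kept = logical(),
                                    removed_by = character(), note = character())))
  }
  if (!"breadth" %in% names(cand)) cand[, breadth := 0L]
  if (!"chrom" %in% names(cand)) cand[, chrom := NA_character_]
  cand[, info_rank := fifelse(is.na(info), -Inf, info)]
  setorder(cand, breadth, p, -info_rank, variant_id)
  kept <- character(); rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    v <- cand$variant_id[i]; blocker <- NA_character_; note <- NA_character_
    for (u in kept) {
      r2 <- ld_lookup(ld, v, u, cand$chrom[i],
                      cand$chrom[match(u, cand$variant_id)])
      if (is.na(r2)) { note <- "no LD information; assumed independent"; next }
      if (r2 >= r2_max) { blocker <- u; break }
    }
    if (is.na(blocker)) kept <- c(kept, v)
    rows[[i]] <- data.table(variant_id = v, kept = is.na(blocker),
                            removed_by = blocker, note = note)
  }
  list(kept = kept, report = rbindlist(rows))
}
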