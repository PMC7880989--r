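## PRS scoring: S_i = sum_j d_ij * beta_j over the harmonized, pruned
## variant set, with dosages counted on the effect allele (2 - d where the
## catalog effect allele is the panel reference allele), then standardized
## within cohort.

#' Assemble a PRS definition from harmonized variants
#'
#' @param site Cancer site code.
#' @param variants Harmonized-variant rows restricted to the kept (pruned)
#'   set for this cancer; needs panel_id, weight, and optionally
#'   flip_dosage, rsid, subphenotype.
#' @param provenance Label recording how the set was derived
#'   (default "full").
#' @return `data.table` of class `prs_definition`.
#' @export
prs_definition <- function(site, variants, provenance = "full") {
  v <- as.data.table(variants)
  if (!"flip_dosage" %in% names(v)) v[, flip_dosage := FALSE]
  if (anyDuplicated(v$panel_id %||% v$variant_id))
    stopf("duplicate variants in PRS definition for %s", site)
  if (!all(is.finite(v$weight))) stopf("non-finite PRS weight for %s", site)
  id_col <- if ("panel_id" %in% names(v)) "panel_id" else "variant_id"
  out <- data.table(site = site, variant_id = v[[id_col]],
                    weight = v$weight, flip_dosage = v$flip_dosage,
                    discovery = if ("subphenotype" %in% names(v))
                      fifelse(is.na(v$subphenotype) | v$subphenotype == "",
                              site, v$subphenotype) else site,
                    provenance = provenance)
  setattr(out, "class", c("prs_definition", class(out)))
  out
}

#' Compute raw PRS from a dosage matrix
#'
#' `S_i = sum_j d*_ij beta_j` with `d* = 2 - d` for flipped variants.
#' Missing dosages are mean-imputed per variant (twice the observed allele
#' frequency) before scoring.
#'
#' @param dosages Samples x variants dosage matrix (named columns).
#' @param prs PRS definition (`data.table` with variant_id, weight,
#'   optionally flip_dosage).
#' @return Named numeric vector of raw scores.
#' @export
compute_prs <- function(dosages, prs) {
  prs <- as.data.table(prs)
  miss <- setdiff(prs$variant_id, colnames(dosages))
  if (length(miss))
    stopf("PRS variant(s) absent from dosage matrix: %s",
          paste(miss, collapse = ", "))
  d <- dosages[, prs$variant_id, drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) {
      na <- is.na(d[, j]); if (any(na)) d[na, j] <- mu[j]
    }
  }
  flip <- if ("flip_dosage" %in% names(prs)) prs$flip_dosage else
    rep(FALSE, nrow(prs))
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  drop(d %*% prs$weight)
}

#' Standardize raw PRS within a population
#'
#' `z_i = (S_i - mu) / sigma`, with mu and sigma (n-1 denominator) computed
#' over the standardization population (default: all samples supplied) and
#' applied to every sample.
#'
#' @param raw Named numeric vector of raw scores.
#' @param mask Optional logical vector or sample-id subset defining the
#'   standardization population.
#' @return List of class `prs_vector`: `raw`, `z`, `mean`, `sd`.
#' @export
standardize_prs <- function(raw, mask = NULL) {
  pop <- if (is.null(mask)) raw
  else if (is.logical(mask)) raw[mask]
  else raw[names(raw) %in% mask]
  if (length(pop) < 2) stopf("standardization population has fewer than 2 samples")
  mu <- mean(pop); sigma <- sd(pop)
  if (sigma == 0) stopf("constant PRS: standard deviation is zero")
  structure(list(raw = raw, z = (raw - mu) / sigma, mean = mu, sd = sigma),
            class = "prs_vector")
}
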