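## Post-processing: genomic-region enrichment of pleiotropic variants
## against the all-PRS-variant background, and the sensitivity reruns
## expressed as PRS variant-set filters (LD-overlap removal, fixed exclusion
## lists, discovery-phenotype restriction).

#' Read a BED region map
#'
#' BED intervals are 0-based half-open; the label is taken from the name
#' column (4th field). Uses `rtracklayer` when available, otherwise a plain
#' tab parse of the first four columns.
#'
#' @param path BED file path.
#' @return `data.table`: chrom, start (0-based), end (exclusive), label.
#' @export
read_region_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      label = gr$name)
  } else {
    out <- fread(path, header = FALSE,
                 col.names = c("chrom", "start", "end", "label"))[, 1:4]
    out[, chrom := as.character(chrom)]
  }
  out[]
}

region_of <- function(chrom, pos, regions) {
  ## pos is 1-based; region [start, end) 0-based half-open
  lab <- rep("other", length(pos))
  for (r in seq_len(nrow(regions))) {
    hit <- chrom == regions$chrom[r] & pos > regions$start[r] &
      pos <= regions$end[r]
    multi <- hit & lab != "other"
    if (any(multi)) stopf("position maps to more than one region label")
    lab[hit] <- regions$label[r]
  }
  lab
}

#' Region enrichment of pleiotropic associations
#'
#' Per region: the proportion of pleiotropic associations falling in it
#' versus the proportion of all PRS variants; the enrichment ratio
#' (pleiotropic / background, undefined when the background count is 0);
#' and size-normalized proportions (each proportion divided by the region
#' span in Mb; NA for the pooled "other" bucket). Denominators are the
#' supplied tables as given — pass deduplicated variants for unique-variant
#' proportions or association rows for per-association proportions.
#'
#' @param pleiotropic `data.table` (chrom, pos) of pleiotropic hits.
#' @param background `data.table` (chrom, pos) of all PRS variants.
#' @param regions Region map from [read_region_bed()] or equivalent.
#' @return `data.table` of class rows: label, n_pleio, prop_pleio, n_all,
#'   prop_all, size_mb, prop_pleio_per_mb, prop_all_per_mb, ratio.
#' @export
region_enrichment <- function(pleiotropic, background, regions) {
  p <- as.data.table(pleiotropic); b <- as.data.table(background)
  regions <- as.data.table(regions)
  p_lab <- region_of(as.character(p$chrom), p$pos, regions)
  b_lab <- region_of(as.character(b$chrom), b$pos, regions)
  labs <- c(regions$label, "other")
  out <- data.table(label = labs,
                    n_pleio = vapply(labs, function(l) sum(p_lab == l), 0L),
                    n_all = vapply(labs, function(l) sum(b_lab == l), 0L))
  out[, prop_pleio := if (nrow(p)) n_pleio / nrow(p) else NA_real_]
  out[, prop_all := if (nrow(b)) n_all / nrow(b) else NA_real_]
  out[, size_mb := c((regions$end - regions$start) / 1e6, NA_real_)]
  out[, prop_pleio_per_mb := prop_pleio / size_mb]
  out[, prop_all_per_mb := prop_all / size_mb]
  out[, ratio := fifelse(n_all > 0, prop_pleio / prop_all, NA_real_)]
  out[]
}

#' Filter a PRS definition for a sensitivity rerun
#'
#' Modes: `"ld_overlap"` removes exposure-PRS variants in LD
#' (r2 >= `r2_min`, default the 0.3 independence threshold) with any variant
#' in `outcome_variants`; `"exclude_set"` removes a fixed variant list (for
#' example tobacco-associated variants); `"restrict_discovery"` keeps only
#' variants whose discovery phenotype matches `label`. The returned
#' definition carries an updated provenance label; downstream scoring,
#' association and meta-analysis are re-run unchanged.
#'
#' @param prs A `prs_definition`.
#' @param mode One of `"ld_overlap"`, `"exclude_set"`,
#'   `"restrict_discovery"`.
#' @param outcome_variants Variant ids known to be associated with the
#'   outcome cancer (ld_overlap mode).
#' @param ld LD source (matrix or long table) for ld_overlap mode.
#' @param r2_min LD threshold for removal (default 0.3).
#' @param exclude Variant ids to drop (exclude_set mode).
#' @param label Discovery label to keep (restrict_discovery mode).
#' @return Filtered `prs_definition`.
#' @export
filter_prs <- function(prs, mode = c("ld_overlap", "exclude_set",
                                     "restrict_discovery"),
                       outcome_variants = NULL, ld = NULL, r2_min = 0.3,
                       exclude = NULL, label = NULL) {
  mode <- match.arg(mode)
  def <- as.data.table(prs)
  keep <- switch(mode,
    ld_overlap = {
      if (is.null(ld)) stopf("ld source required for ld_overlap mode")
      vapply(def$variant_id, function(v) {
        r2s <- vapply(outcome_variants %||% character(),
                      function(u) {
                        r2 <- ld_lookup(ld, v, u)
                        if (is.na(r2)) 0 else r2
                      }, numeric(1))
        !length(r2s) || all(r2s < r2_min)
      }, logical(1))
    },
    exclude_set = !def$variant_id %in% (exclude %||% character()),
    restrict_discovery = {
      if (is.null(label)) stopf("label required for restrict_discovery mode")
      def$discovery == label
    })
  out <- def[keep]
  if (nrow(out) == 0) stopf("empty PRS after filtering (site %s, mode %s)",
                            def$site[1], mode)
  prov <- def$provenance[1] %||% "full"
  if (!endsWith(prov, paste0("+", mode))) prov <- paste0(prov, "+", mode)
  out[, provenance := prov]
  setattr(out, "class", c("prs_definition", class(data.table())))
  out[]
}
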