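## Pipeline orchestration: a declarative JSON config, per-stage functions
## that each read their persisted inputs and write their persisted outputs
## (so any single stage can be re-run reproducibly), and a run() that
## executes curate -> qc -> harmonize -> prune -> score -> assoc -> meta ->
## enrich -> sensitivity. Every output TSV carries a header block with the
## config hash and seed.

default_thresholds <- function() {
  list(gw_p = 5e-8, eur_min = 0.70, proxy_r2 = 0.8, prune_r2 = 0.3,
       maf_min = 0.01, maf_diff_max = 0.10, ambiguous_maf = 0.45,
       min_cases = 650, alpha = 0.05, call_rate_min = 0.97, qc_z_max = 5)
}

## shallow key replacement: unlike modifyList, list-valued keys (e.g. the
## sensitivity mode list) are replaced wholesale, never merged element-wise
replace_keys <- function(base, override) {
  for (k in names(override)) base[[k]] <- override[[k]]
  base
}

## deterministic FNV-1a hash of the canonical config JSON (hex string)
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                        auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a named list; fills defaults, range-checks
#' every threshold and rejects unknown keys.
#'
#' @param x Path to a JSON config or a named list.
#' @return Validated list of class `pipeline_config`.
#' @export
validate_config <- function(x) {
  raw <- if (is.character(x)) jsonlite::fromJSON(x, simplifyVector = TRUE,
                                                 simplifyDataFrame = FALSE)
  else x
  known <- c("input_dir", "out_dir", "cohorts", "thresholds", "sex_specific",
             "analyses", "genotype_format", "regions_bed", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg <- list(
    input_dir = raw$input_dir %||% stopf("config requires input_dir"),
    out_dir = raw$out_dir %||% stopf("config requires out_dir"),
    cohorts = raw$cohorts %||% c("cohortA", "cohortB"),
    thresholds = replace_keys(default_thresholds(),
                              as.list(raw$thresholds %||% list())),
    sex_specific = unlist(raw$sex_specific %||% list()) %||% NULL,
    analyses = replace_keys(list(variant_scan = TRUE, secondary = list(),
                                 sensitivity = list()),
                            as.list(raw$analyses %||% list())),
    genotype_format = raw$genotype_format %||% "tsv",
    regions_bed = raw$regions_bed,
    seed = as.integer(raw$seed %||% 1L))
  th <- cfg$thresholds
  bad_th <- setdiff(names(th), names(default_thresholds()))
  if (length(bad_th)) stopf("unknown threshold(s): %s", paste(bad_th, collapse = ", "))
  chk <- function(name, lo, hi) {
    v <- th[[name]]
    if (!is.numeric(v) || v < lo || v > hi)
      stopf("threshold '%s' = %s out of range [%s, %s]", name, v, lo, hi)
  }
  chk("gw_p", 0, 1); chk("eur_min", 0, 1); chk("proxy_r2", 0, 1)
  chk("prune_r2", 0, 1); chk("maf_min", 0, 0.5); chk("maf_diff_max", 0, 1)
  chk("ambiguous_maf", 0, 0.5); chk("alpha", 0, 1)
  chk("call_rate_min", 0, 1); chk("min_cases", 0, Inf); chk("qc_z_max", 0, Inf)
  if (!cfg$genotype_format %in% c("tsv", "vcf"))
    stopf("genotype_format must be 'tsv' or 'vcf'")
  class(cfg) <- "pipeline_config"
  cfg
}

log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

out_hd <- function(cfg, stage) {
  c(config_hash = config_hash(unclass(cfg)), seed = cfg$seed, stage = stage)
}

opath <- function(cfg, ...) file.path(cfg$out_dir, sprintf(...))
ipath <- function(cfg, ...) file.path(cfg$input_dir, sprintf(...))

read_cohort_dosages <- function(cfg, lab) {
  if (cfg$genotype_format == "vcf")
    read_dosage_vcf(ipath(cfg, "genotypes_%s.vcf", lab))$dosages
  else read_dosage_tsv(ipath(cfg, "dosages_%s.tsv", lab))
}

read_optional <- function(path) if (file.exists(path)) read_tsv_header(path) else NULL

## ---- stages ----------------------------------------------------------------

#' @rdname run_pipeline
#' @export
stage_curate <- function(cfg) {
  cat0 <- read_tsv_header(ipath(cfg, "catalog.tsv"))
  cur <- curate_catalog(cat0, p_max = cfg$thresholds$gw_p,
                        eur_min = cfg$thresholds$eur_min)
  write_tsv_header(cur$kept, opath(cfg, "catalog_curated.tsv"),
                   out_hd(cfg, "curate"))
  write_tsv_header(cur$excluded, opath(cfg, "catalog_excluded.tsv"),
                   out_hd(cfg, "curate"))
  log_msg("curate", "%d records in, %d kept, %d excluded",
          cur$n_input, nrow(cur$kept), nrow(cur$excluded))
  invisible(cur)
}

#' @rdname run_pipeline
#' @export
stage_qc <- function(cfg) {
  for (lab in cfg$cohorts) {
    ph <- read_tsv_header(ipath(cfg, "phenotypes_%s.tsv", lab))
    qc <- sample_qc(ph, call_rate_min = cfg$thresholds$call_rate_min,
                    z_max = cfg$thresholds$qc_z_max)
    write_tsv_header(qc$kept, opath(cfg, "qc_kept_%s.tsv", lab),
                     out_hd(cfg, "qc"))
    write_tsv_header(qc$removed, opath(cfg, "qc_removed_%s.tsv", lab),
                     out_hd(cfg, "qc"))
    log_msg("qc", "%s: %d kept, %d removed", lab, nrow(qc$kept), nrow(qc$removed))
  }
}

#' @rdname run_pipeline
#' @export
stage_harmonize <- function(cfg) {
  cur <- as_catalog(read_tsv_header(opath(cfg, "catalog_curated.tsv")))
  man <- read_tsv_header(ipath(cfg, "manifest.tsv"))
  ld <- read_optional(ipath(cfg, "ld.tsv"))
  if (is.null(ld)) log_msg("harmonize", "no external LD table; proxies unavailable")
  ref <- read_optional(ipath(cfg, "ref_freqs.tsv"))
  for (lab in cfg$cohorts) {
    kept <- read_tsv_header(opath(cfg, "qc_kept_%s.tsv", lab))
    dos <- read_cohort_dosages(cfg, lab)
    dos <- dos[rownames(dos) %in% kept$sample_id, , drop = FALSE]
    h <- harmonize_catalog(cur, man, dos, ld = ld, ref_freqs = ref,
                           r2_min = cfg$thresholds$proxy_r2,
                           ambiguous_maf_max = cfg$thresholds$ambiguous_maf,
                           maf_min = cfg$thresholds$maf_min,
                           maf_diff_max = cfg$thresholds$maf_diff_max)
    write_tsv_header(h$variants, opath(cfg, "harmonized_%s.tsv", lab),
                     out_hd(cfg, "harmonize"))
    write_tsv_header(h$report, opath(cfg, "harmonization_report_%s.tsv", lab),
                     out_hd(cfg, "harmonize"))
    log_msg("harmonize", "%s: %d/%d harmonized", lab, nrow(h$variants), nrow(cur))
  }
}

#' @rdname run_pipeline
#' @export
stage_prune <- function(cfg) {
  lab1 <- cfg$cohorts[1]
  harm <- lapply(cfg$cohorts, function(l)
    read_tsv_header(opath(cfg, "harmonized_%s.tsv", l)))
  names(harm) <- cfg$cohorts
  man <- read_tsv_header(ipath(cfg, "manifest.tsv"))
  ## LD for pruning: in-cohort control genotypes of the first cohort
  kept1 <- read_tsv_header(opath(cfg, "qc_kept_%s.tsv", lab1))
  dos1 <- read_cohort_dosages(cfg, lab1)
  dos1 <- dos1[rownames(dos1) %in% kept1$sample_id, , drop = FALSE]
  shared <- Reduce(intersect, lapply(harm, function(h) h$key))
  h1 <- harm[[lab1]][key %in% shared]
  defs <- list(); reports <- list()
  for (site in sort(unique(h1$phenotype))) {
    hs <- h1[phenotype == site]
    cand <- data.table(variant_id = hs$panel_id, p = hs$p_value,
                       info = hs$info,
                       breadth = fifelse(is.na(hs$subphenotype) |
                                           hs$subphenotype == "", 0L, 1L),
                       chrom = man$chrom[match(hs$panel_id, man$variant_id)])
    ld <- ld_from_dosages(dos1, unique(cand$variant_id))
    pr <- priority_prune(cand, ld, r2_max = cfg$thresholds$prune_r2)
    pr$report[, site := site]
    reports[[site]] <- pr$report
    defs[[site]] <- prs_definition(site, hs[panel_id %in% pr$kept])
  }
  def_dt <- rbindlist(defs)
  write_tsv_header(def_dt, opath(cfg, "prs_definitions.tsv"),
                   out_hd(cfg, "prune"))
  write_tsv_header(rbindlist(reports), opath(cfg, "prune_report.tsv"),
                   out_hd(cfg, "prune"))
  log_msg("prune", "%d variants kept across %d PRS", nrow(def_dt), length(defs))
  invisible(defs)
}

read_prs_definitions <- function(cfg, path = opath(cfg, "prs_definitions.tsv")) {
  dt <- read_tsv_header(path)
  split(dt, by = "site")
}

#' @rdname run_pipeline
#' @export
stage_score <- function(cfg) {
  defs <- read_prs_definitions(cfg)
  for (lab in cfg$cohorts) {
    kept <- read_tsv_header(opath(cfg, "qc_kept_%s.tsv", lab))
    dos <- read_cohort_dosages(cfg, lab)
    dos <- dos[rownames(dos) %in% kept$sample_id, , drop = FALSE]
    rows <- list()
    for (site in names(defs)) {
      raw <- compute_prs(dos, defs[[site]])
      zv <- standardize_prs(raw)
      rows[[site]] <- data.table(sample_id = names(raw), site = site,
                                 raw = raw, z = zv$z)
    }
    write_tsv_header(rbindlist(rows), opath(cfg, "prs_scores_%s.tsv", lab),
                     out_hd(cfg, "score"))
  }
  log_msg("score", "scored %d PRS x %d cohorts", length(defs), length(cfg$cohorts))
}

cohort_assignments <- function(cfg, lab, sites) {
  kept <- read_tsv_header(opath(cfg, "qc_kept_%s.tsv", lab))
  diag <- read_tsv_header(ipath(cfg, "diagnoses_%s.tsv", lab))
  diag[, date := as.Date(date)]
  setNames(lapply(sites, function(s)
    assign_case_control(kept, diag, s, sex_specific = cfg$sex_specific,
                        valid_sites = unique(c(sites, diag$site_code)))),
    sites)
}

#' @rdname run_pipeline
#' @export
stage_assoc <- function(cfg) {
  defs <- read_prs_definitions(cfg)
  sites <- names(defs)
  ## minimum-case rule evaluated on summed cases across cohorts
  case_counts <- setNames(numeric(length(sites)), sites)
  per_cohort <- list()
  for (lab in cfg$cohorts) {
    asg <- cohort_assignments(cfg, lab, sites)
    per_cohort[[lab]] <- asg
    for (s in sites) case_counts[s] <- case_counts[s] + length(asg[[s]]$cases)
  }
  keep_sites <- sites[case_counts >= cfg$thresholds$min_cases]
  dropped <- setdiff(sites, keep_sites)
  if (length(dropped)) {
    log_msg("assoc", "excluding %s (< %d cases across cohorts)",
            paste(sprintf("%s (%d)", dropped, case_counts[dropped]),
                  collapse = ", "), cfg$thresholds$min_cases)
    write_tsv_header(data.table(site = dropped,
                                n_cases = as.integer(case_counts[dropped]),
                                reason = "below_min_cases"),
                     opath(cfg, "excluded_cancers.tsv"), out_hd(cfg, "assoc"))
  }
  for (lab in cfg$cohorts) {
    kept <- read_tsv_header(opath(cfg, "qc_kept_%s.tsv", lab))
    sc <- read_tsv_header(opath(cfg, "prs_scores_%s.tsv", lab))
    z_scores <- lapply(split(sc, by = "site"), function(d)
      setNames(d$z, d$sample_id))
    asg <- per_cohort[[lab]][keep_sites]
    res <- prs_scan(z_scores[keep_sites], asg, kept,
                    sex_specific = cfg$sex_specific, cohort = lab)
    write_tsv_header(res, opath(cfg, "assoc_%s.tsv", lab), out_hd(cfg, "assoc"))
    if (isTRUE(cfg$analyses$variant_scan)) {
      dos <- read_cohort_dosages(cfg, lab)
      dos <- dos[rownames(dos) %in% kept$sample_id, , drop = FALSE]
      vres <- variant_scan(defs[keep_sites], dos, asg, kept,
                           sex_specific = cfg$sex_specific, cohort = lab)
      write_tsv_header(vres, opath(cfg, "variant_assoc_%s.tsv", lab),
                       out_hd(cfg, "assoc"))
    }
    sec <- cfg$analyses$secondary
    if (length(sec)) {
      ## cancer-free controls shared across non-sex-specific cancers
      ctrl_ids <- Reduce(intersect, lapply(asg, `[[`, "controls"))
      prep <- prepare_secondary_phenotypes(kept[kept$sample_id %in% ctrl_ids])
      sres <- secondary_scan(z_scores[keep_sites], prep$samples,
                             traits = unlist(sec), cohort = lab)
      write_tsv_header(sres, opath(cfg, "secondary_assoc_%s.tsv", lab),
                       out_hd(cfg, "assoc"))
    }
  }
  invisible(keep_sites)
}

#' @rdname run_pipeline
#' @export
stage_meta <- function(cfg) {
  alpha <- cfg$thresholds$alpha
  prs_est <- rbindlist(lapply(cfg$cohorts, function(l)
    read_tsv_header(opath(cfg, "assoc_%s.tsv", l))))
  prs_meta <- meta_by_group(prs_est[converged == TRUE])
  n_outcomes <- length(unique(prs_meta$outcome))
  prs_meta <- annotate_significance(prs_meta, m = n_outcomes, alpha = alpha)
  write_tsv_header(prs_meta, opath(cfg, "meta.tsv"), out_hd(cfg, "meta"))
  vpath <- opath(cfg, "variant_assoc_%s.tsv", cfg$cohorts[1])
  if (file.exists(vpath)) {
    vest <- rbindlist(lapply(cfg$cohorts, function(l)
      read_tsv_header(opath(cfg, "variant_assoc_%s.tsv", l))))
    vmeta <- meta_by_group(vest[converged == TRUE],
                           by = c("outcome", "exposure", "origin", "variant_id"))
    ## effective tests = unique variants in the pruned union across PRS
    m_var <- length(unique(vest$variant_id))
    vmeta <- annotate_significance(vmeta, m = m_var, alpha = alpha)
    write_tsv_header(vmeta, opath(cfg, "variant_meta.tsv"), out_hd(cfg, "meta"))
    log_msg("meta", "variant scan: %d meta rows, m = %d unique variants",
            nrow(vmeta), m_var)
  }
  spath <- opath(cfg, "secondary_assoc_%s.tsv", cfg$cohorts[1])
  sfiles <- Filter(file.exists,
                   vapply(cfg$cohorts, function(l)
                     opath(cfg, "secondary_assoc_%s.tsv", l), character(1)))
  if (length(sfiles)) {
    sest <- rbindlist(lapply(sfiles, read_tsv_header))
    smeta <- meta_by_group(sest[converged == TRUE])
    smeta <- annotate_significance(smeta, m = length(unique(smeta$outcome)),
                                   alpha = alpha)
    write_tsv_header(smeta, opath(cfg, "secondary_meta.tsv"), out_hd(cfg, "meta"))
  }
  invisible(prs_meta)
}

#' @rdname run_pipeline
#' @export
stage_enrich <- function(cfg) {
  if (is.null(cfg$regions_bed)) return(invisible(NULL))
  vpath <- opath(cfg, "variant_meta.tsv")
  if (!file.exists(vpath)) return(invisible(NULL))
  vmeta <- read_tsv_header(vpath)
  man <- read_tsv_header(ipath(cfg, "manifest.tsv"))
  defs <- read_prs_definitions(cfg)
  all_ids <- unique(rbindlist(defs)$variant_id)
  background <- man[variant_id %in% all_ids, .(chrom, pos)]
  pleio <- vmeta[significant_bonferroni == TRUE & outcome != origin]
  pleio_pos <- man[match(pleio$variant_id, man$variant_id), .(chrom, pos)]
  regions <- read_region_bed(cfg$regions_bed)
  enr <- region_enrichment(pleio_pos[!is.na(chrom)], background, regions)
  write_tsv_header(enr, opath(cfg, "enrichment.tsv"), out_hd(cfg, "enrich"))
  invisible(enr)
}

#' @rdname run_pipeline
#' @export
stage_sensitivity <- function(cfg) {
  modes <- cfg$analyses$sensitivity
  if (!length(modes)) return(invisible(NULL))
  defs <- read_prs_definitions(cfg)
  for (i in seq_along(modes)) {
    m <- modes[[i]]
    site <- m$site
    def <- prs_definition(site, defs[[site]],
                          provenance = defs[[site]]$provenance[1])
    filt <- switch(m$mode,
      exclude_set = filter_prs(def, "exclude_set", exclude = unlist(m$exclude)),
      restrict_discovery = filter_prs(def, "restrict_discovery", label = m$label),
      ld_overlap = {
        lab1 <- cfg$cohorts[1]
        kept1 <- read_tsv_header(opath(cfg, "qc_kept_%s.tsv", lab1))
        dos1 <- read_cohort_dosages(cfg, lab1)
        dos1 <- dos1[rownames(dos1) %in% kept1$sample_id, , drop = FALSE]
        ids <- unique(c(def$variant_id, unlist(m$outcome_variants)))
        ld <- ld_from_dosages(dos1, intersect(ids, colnames(dos1)))
        filter_prs(def, "ld_overlap",
                   outcome_variants = unlist(m$outcome_variants), ld = ld,
                   r2_min = m$r2_min %||% cfg$thresholds$prune_r2)
      },
      stopf("unknown sensitivity mode '%s'", m$mode))
    est <- list()
    for (lab in cfg$cohorts) {
      kept <- read_tsv_header(opath(cfg, "qc_kept_%s.tsv", lab))
      dos <- read_cohort_dosages(cfg, lab)
      dos <- dos[rownames(dos) %in% kept$sample_id, , drop = FALSE]
      z <- standardize_prs(compute_prs(dos, filt))$z
      asg <- cohort_assignments(cfg, lab, m$outcome %||% site)
      est[[lab]] <- prs_scan(setNames(list(z), site), asg, kept,
                             sex_specific = cfg$sex_specific, cohort = lab)
    }
    res <- annotate_significance(meta_by_group(rbindlist(est)), m = 1,
                                 alpha = cfg$thresholds$alpha)
    res[, `:=`(mode = m$mode, site = site, provenance = filt$provenance[1],
               n_variants = nrow(filt))]
    write_tsv_header(res, opath(cfg, "sensitivity_%02d.tsv", i),
                     out_hd(cfg, "sensitivity"))
    log_msg("sensitivity", "%s/%s: %d variants retained", site, m$mode, nrow(filt))
  }
}

#' Run the full pipeline
#'
#' Executes curate, qc, harmonize, prune, score, assoc, meta, enrich and
#' sensitivity in order. Cancers with fewer than `min_cases` cases summed
#' across cohorts are excluded from the scans with a logged reason. All
#' stage outputs are pure functions of (inputs, config, seed) and every TSV
#' carries a `# config_hash` / `# seed` header.
#'
#' @param config A `pipeline_config` (or path/list accepted by
#'   [validate_config()]).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_curate(cfg)
  stage_qc(cfg)
  stage_harmonize(cfg)
  stage_prune(cfg)
  stage_score(cfg)
  stage_assoc(cfg)
  stage_meta(cfg)
  stage_enrich(cfg)
  stage_sensitivity(cfg)
  invisible(cfg$out_dir)
}
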