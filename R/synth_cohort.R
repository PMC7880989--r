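## Synthetic two-cohort study generator.
##
## Genotypes come from a latent-Gaussian-copula haplotype model: within an LD
## block every variant shares a common latent factor with loading sqrt(rho),
## so latent pairwise correlation is exactly rho; an allele is carried when
## the latent value falls below the allele-frequency quantile, and a dosage is
## the sum of two independent haplotypes. Case status follows a logistic model
## on the standardized true PRS plus covariates; secondary traits are linear
## in the same score. The literature catalog carries planted harmonization
## traps (duplicates, missing effects, strand flips, ambiguous A/T-C/G sites,
## low/discordant MAF, proxy-only and proxyless leads, prunable LD partners)
## whose expected fate is recorded in a trap manifest for exact assertions.

#' Default LD-block layout for the synthetic panel
#'
#' Ten blocks of four variants each; within-block latent correlation cycles
#' through 0, 0.3, 0.6 and 0.9 so realized dosage r-squared spans the
#' independent (<0.3) and linked (>0.3) regimes used by the pruner. Allele
#' frequency is constant within a block (it varies across blocks), keeping
#' realized within-block LD well clear of the pruning threshold on either
#' side.
#'
#' @return List of blocks, each `list(n_variants, freqs, rho)`.
#' @export
default_blocks <- function() {
  rhos <- c(0, 0.3, 0.6, 0.9, 0.6, 0.3, 0, 0.9, 0.3, 0.6)
  freqs <- c(0.15, 0.25, 0.35, 0.45, 0.2, 0.3, 0.4, 0.25, 0.35, 0.2)
  lapply(seq_along(rhos), function(b) {
    list(n_variants = 4L,
         freqs = rep(freqs[b], 4L),
         rho = rhos[b])
  })
}

#' Build and validate a simulation configuration
#'
#' Defaults state the simulated world used throughout the test-suite: two
#' cohorts of 20,000 samples, one cancer with a per-SD log odds ratio of
#' ln(1.3) and one null cancer, baseline prevalence 5%, age and sex effects
#' on disease, and a catalog seeded with one trap of every kind the
#' harmonization and curation stages must catch.
#'
#' @param n_samples Samples per cohort (>= 2).
#' @param blocks List of LD blocks `list(n_variants, freqs, rho)`.
#' @param cancers List of `list(site, theta, alpha, sex)`; `theta` is the true
#'   per-SD log odds ratio, `alpha` the baseline log odds, `sex` one of
#'   "both", "F", "M".
#' @param covariate_effects Named numeric: `age` (per decade, centered at 60)
#'   and `sex` (indicator male) coefficients in the disease model.
#' @param secondary_traits List of `list(name, cancer, slope, noise_sd)`.
#' @param planted_traps Named integer counts of catalog traps.
#' @param planted_qc Named integer counts of planted QC failures.
#' @param cohorts Character vector of cohort labels (two by default).
#' @param specimen_dates One collection `Date` per cohort.
#' @param study_window Two `Date`s bounding diagnosis dates.
#' @param confound_pcs If `TRUE`, PC1 is correlated with genotype block 1
#'   (a switch for confounding tests); default `FALSE`.
#' @param seed Global integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20000L,
                       blocks = default_blocks(),
                       cancers = list(
                         list(site = "lung", theta = log(1.3),
                              alpha = qlogis(0.05), sex = "both"),
                         list(site = "nhl", theta = 0,
                              alpha = qlogis(0.05), sex = "both")),
                       covariate_effects = c(age = 0.03, sex = 0.2),
                       secondary_traits = list(
                         list(name = "bmi", cancer = "lung",
                              slope = 0.1, noise_sd = 1),
                         list(name = "height", cancer = "nhl",
                              slope = 0, noise_sd = 1)),
                       planted_traps = c(duplicate = 2L, missing_effect = 1L,
                                         strand_flip = 2L, ambiguous = 2L,
                                         low_maf = 1L, maf_discordant = 1L,
                                         proxy_only = 2L, proxyless = 1L,
                                         prunable = 2L, nonautosomal = 1L,
                                         low_ancestry = 1L, weak_p = 1L),
                       planted_qc = c(low_call = 2L, het_outlier = 2L,
                                      pc_outlier = 2L, self_report = 5L),
                       cohorts = c("cohortA", "cohortB"),
                       specimen_dates = as.Date(c("2008-01-01", "2009-07-01")),
                       study_window = as.Date(c("2000-01-01", "2015-12-31")),
                       confound_pcs = FALSE,
                       seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 2)
    stopf("n_samples must be >= 2, got %s", n_samples)
  for (b in blocks) {
    if (any(b$freqs <= 0 | b$freqs >= 1))
      stopf("degenerate allele frequency (must be strictly inside (0,1))")
    if (b$rho < 0 || b$rho > 1)
      stopf("within-block correlation rho must be in [0,1], got %s", b$rho)
    if (length(b$freqs) != b$n_variants)
      stopf("block freqs length != n_variants")
  }
  if (length(cancers) < 1) stopf("at least one cancer required")
  n_main_blocks <- length(blocks)
  if (length(cancers) > min(vapply(blocks, `[[`, 1L, "n_variants")))
    stopf("need at least one variant per block per cancer")
  trap_defaults <- c(duplicate = 0L, missing_effect = 0L, strand_flip = 0L,
                     ambiguous = 0L, low_maf = 0L, maf_discordant = 0L,
                     proxy_only = 0L, proxyless = 0L, prunable = 0L,
                     nonautosomal = 0L, low_ancestry = 0L, weak_p = 0L)
  bad <- setdiff(names(planted_traps), names(trap_defaults))
  if (length(bad)) stopf("unknown trap types: %s", paste(bad, collapse = ", "))
  trap_defaults[names(planted_traps)] <- as.integer(planted_traps)
  qc_defaults <- c(low_call = 0L, het_outlier = 0L, pc_outlier = 0L,
                   self_report = 0L)
  qc_defaults[names(planted_qc)] <- as.integer(planted_qc)
  if (length(specimen_dates) != length(cohorts))
    stopf("one specimen date per cohort required")
  cfg <- list(n_samples = as.integer(n_samples), blocks = blocks,
              cancers = cancers, covariate_effects = covariate_effects,
              secondary_traits = secondary_traits,
              planted_traps = trap_defaults, planted_qc = qc_defaults,
              cohorts = cohorts, specimen_dates = specimen_dates,
              study_window = study_window, confound_pcs = confound_pcs,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

## ---- variant manifest ------------------------------------------------------

allele_pairs_plain <- rbind(c("A", "G"), c("C", "T"), c("A", "C"),
                            c("G", "T"), c("T", "C"), c("G", "A"))

#' Build the variant manifest implied by a configuration
#'
#' Main blocks are laid across autosomes (block b on chromosome
#' `((b-1) mod 22)+1`, 50 kb between variants, >= 1 Mb between blocks on the
#' same chromosome). Trap variants are appended as independent singleton
#' blocks with the frequencies their trap requires (ambiguous A/T at 0.47,
#' MAF 0.005, discordant 0.30, proxies at 0.30).
#'
#' @param config A `sim_config`.
#' @return `data.table` with variant_id, chrom, pos, ref, alt, freq, info,
#'   block, rho, role.
#' @export
simulate_manifest <- function(config) {
  set.seed(substream_seed(config$seed, "manifest"))
  rows <- list(); vid <- 0L
  nxt_id <- function() { vid <<- vid + 1L; sprintf("rs%06d", 100000L + vid) }
  for (b in seq_along(config$blocks)) {
    blk <- config$blocks[[b]]
    chrom <- ((b - 1L) %% 22L) + 1L
    base <- 1e6 * (1 + 2 * ((b - 1L) %/% 22L))
    for (j in seq_len(blk$n_variants)) {
      al <- allele_pairs_plain[((b + j) %% nrow(allele_pairs_plain)) + 1L, ]
      rows[[length(rows) + 1L]] <- data.table(
        variant_id = nxt_id(), chrom = as.character(chrom),
        pos = as.integer(base + j * 5e4), ref = al[1], alt = al[2],
        freq = blk$freqs[j], block = b, rho = blk$rho, role = "main")
    }
  }
  tr <- config$planted_traps
  add_trap <- function(role, freq, ref, alt, k) {
    b <- length(config$blocks) + length(rows)  # unique singleton block id
    chrom <- as.character(((b - 1L) %% 22L) + 1L)
    rows[[length(rows) + 1L]] <<- data.table(
      variant_id = nxt_id(), chrom = chrom,
      pos = as.integer(9e6 + (length(rows)) * 1e5), ref = ref, alt = alt,
      freq = freq, block = b, rho = 0, role = role)
  }
  for (k in seq_len(tr[["ambiguous"]]))      add_trap("trap_ambiguous", 0.47, "A", "T", k)
  for (k in seq_len(tr[["low_maf"]]))        add_trap("trap_low_maf", 0.005, "C", "T", k)
  for (k in seq_len(tr[["maf_discordant"]])) add_trap("trap_maf_discordant", 0.30, "A", "G", k)
  for (k in seq_len(tr[["proxy_only"]]))     add_trap("trap_proxy", 0.30, "G", "T", k)
  man <- rbindlist(rows)
  man[, info := round(runif(.N, 0.85, 0.999), 4)]
  setcolorder(man, c("variant_id", "chrom", "pos", "ref", "alt",
                     "freq", "info", "block", "rho", "role"))
  man[]
}

#' True per-cancer PRS definitions of the simulated world
#'
#' Cancer k takes variant k of every main LD block (so its variants are
#' mutually independent and survive pruning intact) plus, for the first
#' cancer, any planted proxy panel variants (their catalog records point at
#' an absent lead that harmonization must resolve back to the proxy).
#' Weights are log odds ratios drawn uniformly from +/-[0.08, 0.30].
#'
#' @param manifest From [simulate_manifest()].
#' @param config A `sim_config`.
#' @return Named list of `data.table`s (site, variant_id, weight, discovery).
#' @export
true_prs_definitions <- function(manifest, config) {
  set.seed(substream_seed(config$seed, "weights"))
  defs <- list()
  for (k in seq_along(config$cancers)) {
    site <- config$cancers[[k]]$site
    ids <- manifest[role == "main",
                    .SD[k, variant_id], by = block][["V1"]]
    if (k == 1L) ids <- c(ids, manifest[role == "trap_proxy", variant_id])
    w <- round(runif(length(ids), 0.08, 0.30), 4) *
      sample(c(-1, 1), length(ids), replace = TRUE)
    defs[[site]] <- data.table(site = site, variant_id = ids, weight = w,
                               discovery = site)
  }
  defs
}

## ---- genotypes & covariates ------------------------------------------------

draw_block_dosages <- function(n, freqs, rho) {
  m <- length(freqs)
  q <- qnorm(freqs)
  hap <- function() {
    z0 <- rnorm(n)
    lat <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    sweep(lat, 2, q, `<`) * 1L
  }
  hap() + hap()
}

#' Simulate one cohort's genotypes, covariates and QC metrics
#'
#' @param config A `sim_config`.
#' @param cohort Cohort index (1-based) or label.
#' @return Object of class `syn_cohort`: list with `label`, `dosages`
#'   (samples x variants matrix in `[0,2]`), `manifest`, `samples`
#'   (covariates, QC metrics, raw secondary measurements), `specimen_date`.
#' @export
simulate_genotypes <- function(config, cohort = 1L) {
  if (is.character(cohort)) cohort <- match(cohort, config$cohorts)
  label <- config$cohorts[cohort]
  man <- simulate_manifest(config)
  n <- config$n_samples
  set.seed(substream_seed(config$seed, paste0("geno", cohort)))
  dos <- matrix(0, n, nrow(man),
                dimnames = list(sprintf("%s_S%05d", label, seq_len(n)),
                                man$variant_id))
  for (b in unique(man$block)) {
    idx <- which(man$block == b)
    dos[, idx] <- draw_block_dosages(n, man$freq[idx], man$rho[idx[1]])
  }
  set.seed(substream_seed(config$seed, paste0("covar", cohort)))
  samples <- data.table(
    sample_id = rownames(dos),
    sex = ifelse(rbinom(n, 1, 0.5) == 1, "M", "F"),
    age = round(pmin(pmax(rnorm(n, 60, 8), 40), 80), 1),
    batch = sample(c("batch1", "batch2"), n, replace = TRUE),
    call_rate = round(runif(n, 0.985, 1), 4),
    het = rnorm(n))
  pcs <- matrix(rnorm(n * 10), n, 10)
  if (isTRUE(config$confound_pcs)) {
    g1 <- scale(dos[, man[block == 1, variant_id[1]]])[, 1]
    pcs[, 1] <- 0.6 * g1 + sqrt(1 - 0.36) * pcs[, 1]
  }
  colnames(pcs) <- paste0("PC", 1:10)
  samples <- cbind(samples, as.data.table(pcs))
  ## raw secondary measurements exercised by the phenotype-prep stage
  samples[, waist := round(rnorm(n, 90, 10), 1)]
  samples[, hip := round(rnorm(n, 100, 8), 1)]
  samples[, crp := round(exp(rnorm(n, 0.5, 0.6)), 3)]
  samples[, self_report_cancer := FALSE]
  samples[, death_cause_cancer := FALSE]
  samples[, specimen_date := config$specimen_dates[cohort]]
  qc <- config$planted_qc
  ord <- sample(n)  # disjoint planted QC failures
  take <- function(k) { out <- ord[seq_len(k)]; ord <<- ord[-seq_len(k)]; out }
  if (qc[["low_call"]] > 0) samples[take(qc[["low_call"]]), call_rate := 0.96]
  if (qc[["het_outlier"]] > 0) samples[take(qc[["het_outlier"]]), het := 8]
  if (qc[["pc_outlier"]] > 0) samples[take(qc[["pc_outlier"]]), PC2 := 8]
  structure(list(label = label, dosages = dos, manifest = man,
                 samples = samples,
                 specimen_date = config$specimen_dates[cohort]),
            class = "syn_cohort")
}

#' Simulate case status and diagnosis dates from the logistic model
#'
#' For each configured cancer the linear predictor is
#' `alpha + theta * z + gamma_age * (age-60)/10 + gamma_sex * I(male)`
#' (plus nothing else; PCs are nuisance covariates uncorrelated with disease
#' unless the confounding switch is on), where `z` is the within-cohort
#' standardized true PRS. Sex-specific cancers only afflict the relevant sex.
#' Each diagnosis gets a date uniform over the study window, so incident and
#' prevalent cases both occur relative to the cohort's specimen date.
#'
#' @param cohort A `syn_cohort`.
#' @param prs_defs From [true_prs_definitions()].
#' @param config A `sim_config`.
#' @return The cohort with `diagnoses` (sample_id, site_code, date) and
#'   updated `samples` (self-report flags planted among non-cases).
#' @export
simulate_phenotypes <- function(cohort, prs_defs, config) {
  ci <- match(cohort$label, config$cohorts)
  set.seed(substream_seed(config$seed, paste0("pheno", ci)))
  s <- cohort$samples
  n <- nrow(s)
  diag_rows <- list()
  win <- as.integer(config$study_window)
  for (cc in config$cancers) {
    def <- prs_defs[[cc$site]]
    raw <- compute_prs(cohort$dosages, def)
    z <- standardize_prs(raw)$z
    eta <- cc$alpha + cc$theta * z +
      config$covariate_effects[["age"]] * (s$age - 60) / 10 +
      config$covariate_effects[["sex"]] * (s$sex == "M")
    y <- rbinom(n, 1, plogis(eta))
    if (!is.null(cc$sex) && cc$sex != "both") y[s$sex != cc$sex] <- 0L
    idx <- which(y == 1L)
    if (length(idx))
      diag_rows[[cc$site]] <- data.table(
        sample_id = s$sample_id[idx], site_code = cc$site,
        date = as.Date(round(runif(length(idx), win[1], win[2])),
                       origin = "1970-01-01"))
  }
  diagnoses <- if (length(diag_rows)) rbindlist(diag_rows) else
    data.table(sample_id = character(), site_code = character(),
               date = as.Date(character()))
  setorder(diagnoses, sample_id, date, site_code)
  ## plant registry-free self-reports / death causes among non-cases: these
  ## samples must be excluded from every control set
  free <- setdiff(s$sample_id, diagnoses$sample_id)
  k <- min(config$planted_qc[["self_report"]], length(free))
  if (k > 0) {
    pick <- sample(free, k)
    s[sample_id %in% pick[seq_len(ceiling(k / 2))], self_report_cancer := TRUE]
    s[sample_id %in% pick[-seq_len(ceiling(k / 2))], death_cause_cancer := TRUE]
  }
  cohort$samples <- s
  cohort$diagnoses <- diagnoses
  cohort
}

#' Simulate secondary quantitative traits linear in a PRS
#'
#' `trait = slope * z + N(0, noise_sd)`, `z` the standardized true PRS of the
#' trait's cancer.
#'
#' @inheritParams simulate_phenotypes
#' @return Cohort with one extra numeric column per configured trait.
#' @export
simulate_secondary_traits <- function(cohort, prs_defs, config) {
  ci <- match(cohort$label, config$cohorts)
  set.seed(substream_seed(config$seed, paste0("traits", ci)))
  for (tr in config$secondary_traits) {
    z <- standardize_prs(compute_prs(cohort$dosages, prs_defs[[tr$cancer]]))$z
    val <- tr$slope * z + if (tr$noise_sd > 0)
      rnorm(nrow(cohort$samples), 0, tr$noise_sd) else 0
    cohort$samples[, (tr$name) := val]
  }
  cohort
}

## ---- literature catalog with planted traps ---------------------------------

#' Simulate the literature association catalog, traps and LD sidecars
#'
#' Emits one genome-wide-significant record per true PRS variant plus planted
#' traps. Kept/removed expectations per trap are recorded in the returned
#' `traps` manifest (columns: trap_type, record_id, rsid, stage, expect).
#'
#' @param manifest From [simulate_manifest()].
#' @param prs_defs From [true_prs_definitions()].
#' @param config A `sim_config`.
#' @return List: `catalog` (one row per record), `traps`, `ld` (var1, var2,
#'   r2 for absent leads and their proxies), `ref_freqs` (variant_id, alt
#'   allele freq of the reference panel stand-in).
#' @export
simulate_catalog <- function(manifest, prs_defs, config) {
  set.seed(substream_seed(config$seed, "catalog"))
  man <- manifest
  tr <- config$planted_traps
  recs <- list(); traps <- list(); ld <- list()
  rid <- 0L
  new_rec <- function(rsid, chrom, pos, ea, oa, or_, p, phen, sub = NA_character_,
                      anc = 1.0, info = NA_real_, study = NULL) {
    rid <<- rid + 1L
    data.table(record_id = sprintf("rec%04d", rid),
               study_id = study %||% sprintf("SYN%04d", rid),
               phenotype = phen, subphenotype = sub, ancestry_label = "EUR",
               ancestry_eur_fraction = anc, rsid = rsid,
               chrom = chrom, pos = pos,
               effect_allele = ea, other_allele = oa,
               effect = or_, effect_type = "OR",
               p_value = p, imputation_info = info)
  }
  add_trap <- function(type, rec, stage, expect) {
    traps[[length(traps) + 1L]] <<- data.table(
      trap_type = type, record_id = rec$record_id, rsid = rec$rsid,
      stage = stage, expect = expect)
  }
  proxy_ids <- man[role == "trap_proxy", variant_id]
  proxy_used <- 0L
  ## main records: one per true PRS variant, alt allele as the effect allele
  for (site in names(prs_defs)) {
    def <- prs_defs[[site]]
    for (i in seq_len(nrow(def))) {
      v <- man[variant_id == def$variant_id[i]]
      p <- 10^(-runif(1, 9, 30))
      if (v$role == "trap_proxy") {
        ## catalog reports an absent lead; the in-panel proxy carries the truth
        proxy_used <- proxy_used + 1L
        lead <- sprintf("rsLEAD%02d", proxy_used)
        rec <- new_rec(lead, v$chrom, v$pos + 1000L, v$alt, v$ref,
                       exp(def$weight[i]), p, site, info = v$info)
        ld[[length(ld) + 1L]] <- data.table(var1 = lead, var2 = v$variant_id,
                                            r2 = 0.9)
        add_trap("proxy_only", rec, "harmonization", "proxy")
      } else {
        rec <- new_rec(v$variant_id, v$chrom, v$pos, v$alt, v$ref,
                       exp(def$weight[i]), p, site, info = v$info)
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  main <- rbindlist(recs)
  first_site <- names(prs_defs)[1]
  man_main1 <- merge(prs_defs[[first_site]], man, by = "variant_id")
  ## strand-flip traps: recode existing non-ambiguous records in complement
  flip_targets <- main[phenotype == first_site &
                         !is_ambiguous_pair(effect_allele, other_allele) &
                         !startsWith(rsid, "rsLEAD")]
  for (k in seq_len(min(tr[["strand_flip"]], nrow(flip_targets)))) {
    id <- flip_targets$record_id[k]
    main[record_id == id,
         `:=`(effect_allele = complement_allele(effect_allele),
              other_allele = complement_allele(other_allele))]
    traps[[length(traps) + 1L]] <- data.table(
      trap_type = "strand_flip", record_id = id,
      rsid = main[record_id == id, rsid],
      stage = "harmonization", expect = "kept")
  }
  extra <- list()
  ## dedupe traps: same key, larger p (loses) or smaller p without effect
  dup_targets <- main[phenotype == first_site & !startsWith(rsid, "rsLEAD")]
  for (k in seq_len(tr[["duplicate"]])) {
    t0 <- dup_targets[k]
    rec <- new_rec(t0$rsid, t0$chrom, t0$pos, t0$effect_allele,
                   t0$other_allele, t0$effect, t0$p_value * 1e3,
                   t0$phenotype, info = t0$imputation_info,
                   study = sprintf("DUP%03d", k))
    extra[[length(extra) + 1L]] <- rec
    add_trap("duplicate", rec, "dedupe", "removed")
  }
  for (k in seq_len(tr[["missing_effect"]])) {
    t0 <- dup_targets[tr[["duplicate"]] + k]
    rec <- new_rec(t0$rsid, t0$chrom, t0$pos, t0$effect_allele,
                   t0$other_allele, NA_real_, t0$p_value / 10,
                   t0$phenotype, info = t0$imputation_info,
                   study = sprintf("NOEFF%03d", k))
    extra[[length(extra) + 1L]] <- rec
    add_trap("missing_effect", rec, "dedupe", "removed")
  }
  ## harmonization drop traps (records on dedicated trap panel variants)
  harm_trap <- function(trap_role, type) {
    vs <- man[role == paste0("trap_", trap_role)]
    for (k in seq_len(nrow(vs))) {
      v <- vs[k]
      rec <- new_rec(v$variant_id, v$chrom, v$pos, v$alt, v$ref, 1.05,
                     10^(-runif(1, 9, 12)), first_site, info = v$info)
      extra[[length(extra) + 1L]] <<- rec
      add_trap(type, rec, "harmonization", "removed")
    }
  }
  harm_trap("ambiguous", "ambiguous")
  harm_trap("low_maf", "low_maf")
  harm_trap("maf_discordant", "maf_discordant")
  for (k in seq_len(tr[["proxyless"]])) {
    rec <- new_rec(sprintf("rsNOPROXY%02d", k), "21",
                   as.integer(4.2e7 + k * 1e5), "A", "G", 1.10,
                   10^(-runif(1, 9, 12)), first_site)
    extra[[length(extra) + 1L]] <- rec
    add_trap("proxyless", rec, "harmonization", "removed")
  }
  ## prunable traps: spare variants in a rho=0.9 block of cancer 1, larger p
  hi_blocks <- man[role == "main" & rho >= 0.9, unique(block)]
  spare <- man[role == "main" & block %in% hi_blocks &
                 !variant_id %in% unlist(lapply(prs_defs, `[[`, "variant_id"))]
  for (k in seq_len(min(tr[["prunable"]], nrow(spare)))) {
    v <- spare[k]
    rec <- new_rec(v$variant_id, v$chrom, v$pos, v$alt, v$ref, 1.08,
                   2e-8, first_site, sub = "subtype", info = v$info)
    extra[[length(extra) + 1L]] <- rec
    add_trap("prunable", rec, "prune", "removed")
  }
  ## curation traps
  for (k in seq_len(tr[["nonautosomal"]])) {
    rec <- new_rec(sprintf("rsCHRX%02d", k), "X", as.integer(1e6 + k * 1e5),
                   "A", "G", 1.2, 1e-10, first_site)
    extra[[length(extra) + 1L]] <- rec
    add_trap("nonautosomal", rec, "curation", "removed")
  }
  for (k in seq_len(tr[["low_ancestry"]])) {
    rec <- new_rec(sprintf("rsANC%02d", k), "9", as.integer(2e6 + k * 1e5),
                   "C", "T", 1.2, 1e-10, first_site, anc = 0.60)
    extra[[length(extra) + 1L]] <- rec
    add_trap("low_ancestry", rec, "curation", "removed")
  }
  for (k in seq_len(tr[["weak_p"]])) {
    rec <- new_rec(sprintf("rsWEAK%02d", k), "10", as.integer(3e6 + k * 1e5),
                   "G", "T", 1.2, 6e-8, first_site)
    extra[[length(extra) + 1L]] <- rec
    add_trap("weak_p", rec, "curation", "removed")
  }
  catalog <- rbindlist(c(list(main), extra))
  setorder(catalog, record_id)
  ## reference panel stand-in frequencies; discordant traps claim MAF off by ~0.18
  ref <- man[, .(variant_id, ref_alt_freq = freq)]
  ref[variant_id %in% man[role == "trap_maf_discordant", variant_id],
      ref_alt_freq := 0.52]
  list(catalog = catalog,
       traps = rbindlist(traps),
       ld = if (length(ld)) rbindlist(ld) else
         data.table(var1 = character(), var2 = character(), r2 = numeric()),
       ref_freqs = ref)
}

#' Simulate the full two-cohort study
#'
#' Convenience wrapper running genotype, phenotype, secondary-trait and
#' catalog generation for every configured cohort.
#'
#' @param config A `sim_config`.
#' @return List: `config`, `cohorts` (list of `syn_cohort`), `manifest`,
#'   `true_prs`, `catalog`, `traps`, `ld`, `ref_freqs`.
#' @export
simulate_study <- function(config) {
  manifest <- simulate_manifest(config)
  true_prs <- true_prs_definitions(manifest, config)
  cohorts <- lapply(seq_along(config$cohorts), function(ci) {
    co <- simulate_genotypes(config, ci)
    co <- simulate_phenotypes(co, true_prs, config)
    simulate_secondary_traits(co, true_prs, config)
  })
  names(cohorts) <- config$cohorts
  cat_out <- simulate_catalog(manifest, true_prs, config)
  c(list(config = config, cohorts = cohorts, manifest = manifest,
         true_prs = true_prs), cat_out)
}
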