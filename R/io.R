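## File-format glue: TSV fixtures with a reproducibility header block, a
## minimal VCF 4.2 dosage writer (DS format field), and dosage readers for
## both the TSV and VCF routes (VCF parsed with VariantAnnotation when
## available; DS preferred, GT fallback as alt-allele count).

#' Write a TSV with a commented reproducibility header
#'
#' @param x Table to write.
#' @param path Output path.
#' @param header Named character vector written as `# key: value` lines
#'   (config hash, seed, stage).
#' @export
write_tsv_header <- function(x, path, header = c()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  close(con); on.exit()
  fwrite(as.data.table(x), path, sep = "\t", append = length(header) > 0,
         col.names = TRUE, quote = FALSE)
}

#' Read a TSV written by [write_tsv_header()]
#'
#' @param path File path.
#' @return `data.table` (comment lines skipped).
#' @export
read_tsv_header <- function(path) {
  n <- max_comment_lines(path)
  if (length(readLines(path, n = n + 1L)) <= n) return(data.table())
  fread(path, sep = "\t", skip = n, header = TRUE)
}

max_comment_lines <- function(path) {
  n <- 0L
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l) || !startsWith(l, "#")) break
    n <- n + 1L
  }
  n
}

#' Write a cohort's dosages as a minimal VCF with a DS FORMAT field
#'
#' Emits a VCF 4.2 text file with one sample column per individual, GT set
#' to `./.` (dosages may be fractional) and DS carrying the expected
#' alt-allele count.
#'
#' @param dosages Samples x variants matrix.
#' @param manifest Variant manifest (variant_id, chrom, pos, ref, alt).
#' @param path Output path (plain text).
#' @export
write_dosage_vcf <- function(dosages, manifest, path) {
  man <- as.data.table(manifest)
  stopifnot(all(man$variant_id %in% colnames(dosages)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=prspleio",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Expected alternate allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")), con)
  for (i in seq_len(nrow(man))) {
    ds <- formatC(dosages[, man$variant_id[i]], format = "g", digits = 6)
    writeLines(paste(c(man$chrom[i], man$pos[i], man$variant_id[i],
                       man$ref[i], man$alt[i], ".", "PASS", ".", "GT:DS",
                       paste0("./.:", ds)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a dosage matrix from a VCF (DS preferred, GT fallback)
#'
#' Parses with `VariantAnnotation::readVcf` when installed, otherwise with a
#' plain-text fallback that understands the files written by
#' [write_dosage_vcf()]. GT genotypes are converted to alt-allele counts.
#'
#' @param path VCF path.
#' @return List: `dosages` (samples x variants), `manifest` (variant_id,
#'   chrom, pos, ref, alt).
#' @export
read_dosage_vcf <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    man <- data.table(
      variant_id = names(rr),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) paste(as.character(a), collapse = ","),
                   character(1)))
    g <- VariantAnnotation::geno(v)
    if ("DS" %in% names(g)) {
      dm <- t(matrix(as.numeric(g$DS), nrow = nrow(g$DS)))
      dimnames(dm) <- list(colnames(g$DS), rownames(g$DS))
    } else if ("GT" %in% names(g)) {
      gt <- g$GT
      cnt <- matrix(vapply(gt, gt_to_count, numeric(1)), nrow = nrow(gt))
      dm <- t(cnt); dimnames(dm) <- list(colnames(gt), rownames(gt))
    } else stopf("VCF has neither DS nor GT")
    return(list(dosages = dm, manifest = man))
  }
  read_dosage_vcf_text(path)
}

gt_to_count <- function(gt) {
  gt <- sub(":.*", "", gt)
  if (gt %in% c(".", "./.", ".|.")) return(NA_real_)
  sum(as.integer(strsplit(gt, "[/|]")[[1]]) > 0)
}

read_dosage_vcf_text <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- strsplit(lines[(hdr + 1):length(lines)], "\t")
  man <- rbindlist(lapply(body, function(f)
    data.table(variant_id = f[3], chrom = f[1], pos = as.integer(f[2]),
               ref = f[4], alt = f[5])))
  fmt_ds <- function(f) {
    keys <- strsplit(f[9], ":")[[1]]
    ds_i <- match("DS", keys); gt_i <- match("GT", keys)
    vapply(f[-(1:9)], function(cell) {
      parts <- strsplit(cell, ":")[[1]]
      if (!is.na(ds_i)) as.numeric(parts[ds_i]) else gt_to_count(parts[gt_i])
    }, numeric(1), USE.NAMES = FALSE)
  }
  dm <- vapply(body, fmt_ds, numeric(length(samples)))
  dimnames(dm) <- list(samples, man$variant_id)
  list(dosages = dm, manifest = man)
}

#' Write all fixtures for one simulated study to a directory
#'
#' Emits, per cohort: dosage TSV (and optionally VCF), phenotype TSV,
#' diagnosis TSV; plus shared manifest, catalog, trap-manifest, LD and
#' reference-frequency TSVs.
#'
#' @param study From [simulate_study()].
#' @param dir Output directory (created if missing).
#' @param vcf Also write per-cohort VCFs (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hd <- c(seed = study$config$seed)
  write_tsv_header(study$manifest, file.path(dir, "manifest.tsv"), hd)
  write_tsv_header(study$catalog, file.path(dir, "catalog.tsv"), hd)
  write_tsv_header(study$traps, file.path(dir, "traps.tsv"), hd)
  write_tsv_header(study$ld, file.path(dir, "ld.tsv"), hd)
  write_tsv_header(study$ref_freqs, file.path(dir, "ref_freqs.tsv"), hd)
  defs <- rbindlist(study$true_prs)
  write_tsv_header(defs, file.path(dir, "true_prs.tsv"), hd)
  for (lab in names(study$cohorts)) {
    co <- study$cohorts[[lab]]
    dt <- as.data.table(co$dosages, keep.rownames = "sample_id")
    write_tsv_header(dt, file.path(dir, sprintf("dosages_%s.tsv", lab)), hd)
    write_tsv_header(co$samples, file.path(dir, sprintf("phenotypes_%s.tsv", lab)), hd)
    write_tsv_header(co$diagnoses, file.path(dir, sprintf("diagnoses_%s.tsv", lab)), hd)
    if (vcf)
      write_dosage_vcf(co$dosages, co$manifest,
                       file.path(dir, sprintf("genotypes_%s.vcf", lab)))
  }
  invisible(dir)
}

#' Read a dosage TSV (samples in rows, first column sample_id)
#'
#' @param path File path.
#' @return Samples x variants numeric matrix.
#' @export
read_dosage_tsv <- function(path) {
  dt <- read_tsv_header(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}
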