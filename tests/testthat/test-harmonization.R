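mini_panel <- function() {
  data.frame(variant_id = c("rs1", "rs2", "rs3"),
             chrom = c("1", "1", "2"),
             pos = c(1000L, 2000L, 5000L),
             ref = c("A", "C", "G"), alt = c("G", "T", "T"))
}

rec_row <- function(rsid = "rs1", chrom = "1", pos = 1000L, ea = "G",
                    oa = "A", p = 1e-10, or_ = 1.2) {
  as_catalog(data.frame(study_id = "S", phenotype = "lung", rsid = rsid,
                        chrom = chrom, pos = pos, effect_allele = ea,
                        other_allele = oa, effect = or_, effect_type = "OR",
                        p_value = p))[1]
}

test_that("matching: direct by id, by position, then best proxy", {
  panel <- mini_panel()
  expect_equal(match_or_proxy(rec_row("rs1"), panel)$matched_via, "direct")
  byp <- match_or_proxy(rec_row("rsX", chrom = "1", pos = 2000L), panel)
  expect_equal(byp$matched_via, "position")
  expect_equal(byp$panel_id, "rs2")
  ld <- data.frame(var1 = c("rsY", "rsY"), var2 = c("rs1", "rs2"),
                   r2 = c(0.85, 0.92))
  pr <- match_or_proxy(rec_row("rsY", chrom = "1", pos = 1500L), panel, ld)
  expect_equal(pr$matched_via, "proxy")
  expect_equal(pr$panel_id, "rs2")          # highest r2 wins
  expect_equal(pr$proxy_r2, 0.92)
  ## below threshold -> dropped
  ld_low <- data.frame(var1 = "rsZ", var2 = "rs1", r2 = 0.75)
  m <- match_or_proxy(rec_row("rsZ", chrom = "1", pos = 1200L), panel, ld_low)
  expect_false(m$matched)
  expect_match(m$reason, "no proxy")
  ## no LD source at all
  m2 <- match_or_proxy(rec_row("rsZ", chrom = "1", pos = 1200L), panel)
  expect_false(m2$matched)
  expect_equal(m2$reason, "no LD information")
  ## proxy ties on r2 break by distance
  ld_tie <- data.frame(var1 = c("rsT", "rsT"), var2 = c("rs1", "rs2"),
                       r2 = c(0.9, 0.9))
  tie <- match_or_proxy(rec_row("rsT", chrom = "1", pos = 1900L), panel, ld_tie)
  expect_equal(tie$panel_id, "rs2")
})

test_that("allele reconciliation: direct, flip, strand flip, mismatch", {
  panel <- mini_panel()
  p1 <- panel[1, ]  # ref A, alt G
  direct <- harmonize_alleles(rec_row(ea = "G", oa = "A"), p1, 0.3)
  expect_true(direct$ok); expect_false(direct$flip_dosage)
  expect_false(direct$strand_flipped)
  flip <- harmonize_alleles(rec_row(ea = "A", oa = "G"), p1, 0.3)
  expect_true(flip$ok); expect_true(flip$flip_dosage)
  strand <- harmonize_alleles(rec_row(ea = "C", oa = "T"), p1, 0.3)
  expect_true(strand$ok); expect_true(strand$strand_flipped)
  expect_false(strand$flip_dosage)          # complement of C is G = alt
  strand2 <- harmonize_alleles(rec_row(ea = "T", oa = "C"), p1, 0.3)
  expect_true(strand2$ok); expect_true(strand2$flip_dosage)
  bad <- harmonize_alleles(rec_row(ea = "C", oa = "A"), p1, 0.3)
  expect_false(bad$ok); expect_equal(bad$reason, "allele_mismatch")
})

test_that("ambiguous A/T and C/G variants are dropped at MAF >= 0.45 only", {
  at_panel <- data.frame(variant_id = "rsA", chrom = "1", pos = 10L,
                         ref = "A", alt = "T")
  rec <- rec_row("rsA", ea = "T", oa = "A")
  hi <- harmonize_alleles(rec, at_panel, cohort_maf = 0.48)
  expect_false(hi$ok)
  expect_equal(hi$reason, "ambiguous_alleles_high_maf")
  at_boundary <- harmonize_alleles(rec, at_panel, cohort_maf = 0.45)
  expect_false(at_boundary$ok)              # threshold is >= 0.45
  lo <- harmonize_alleles(rec, at_panel, cohort_maf = 0.20)
  expect_true(lo$ok)
})

test_that("frequency filters: MAF floor, reference presence and concordance", {
  p1 <- data.frame(variant_id = "rs1", ref = "A", alt = "G")
  ref <- data.frame(variant_id = "rs1", ref_alt_freq = 0.45)
  expect_false(apply_frequency_filters(p1, 0.005, ref)$ok)
  expect_equal(apply_frequency_filters(p1, 0.005, ref)$reason, "maf_below_min")
  disc <- apply_frequency_filters(p1, 0.30, ref)
  expect_false(disc$ok)                     # |0.30 - 0.45| = 0.15 > 0.10
  expect_equal(disc$reason, "maf_discordant_with_reference")
  ok <- apply_frequency_filters(p1, 0.40, ref)
  expect_true(ok$ok); expect_equal(ok$ref_maf, 0.45)
  absent <- apply_frequency_filters(data.frame(variant_id = "rsQ", ref = "A",
                                               alt = "G"), 0.25, ref)
  expect_equal(absent$reason, "absent_from_reference")
  multi <- apply_frequency_filters(data.frame(variant_id = "rs1", ref = "A",
                                              alt = "G,T"), 0.25, ref)
  expect_equal(multi$reason, "not_biallelic")
  ## no reference table: concordance skipped with a warning
  expect_warning(out <- apply_frequency_filters(p1, 0.25, NULL),
                 "reference")
  expect_true(out$ok)
})

test_that("harmonizing the planted-trap fixture drops exactly the planted set", {
  st <- tiny_study()
  cur <- curate_catalog(st$catalog)
  dos <- tiny_dosages(st, 1L)
  h <- harmonize_catalog(cur$kept, st$manifest, dos, ld = st$ld,
                         ref_freqs = st$ref_freqs)
  planted <- st$traps[st$traps$stage == "harmonization" &
                        st$traps$expect == "removed", ][["record_id"]]
  dropped <- h$report[h$report$outcome == "dropped", ][["record_id"]]
  expect_setequal(dropped, planted)
  ## counts conserve: every curated record has exactly one report row
  expect_equal(nrow(h$report), nrow(cur$kept))
  expect_equal(nrow(h$variants) + length(dropped), nrow(cur$kept))
  ## proxy-only leads resolved to their planted proxies at r2 = 0.9
  proxies <- h$variants[h$variants$matched_via == "proxy", ]
  expect_equal(nrow(proxies),
               sum(st$traps$trap_type == "proxy_only"))
  expect_true(all(proxies$proxy_r2 >= 0.8))
  ## strand-flip traps are kept and flagged
  flips <- st$traps[st$traps$trap_type == "strand_flip", ][["record_id"]]
  expect_true(all(h$variants$strand_flipped[match(flips, h$variants$record_id)]))
})

test_that("allele-coding invariance: complement dosage vs negated weight", {
  st <- tiny_study()
  dos <- tiny_dosages(st, 1L)
  def <- st$true_prs$lung[1:5, ]
  ## representation A: count effect allele on 2-d for variant 1
  defA <- data.table::copy(def)
  defA$flip_dosage <- c(TRUE, rep(FALSE, 4))
  ## representation B: same variant with negated weight on d
  defB <- data.table::copy(def)
  defB$weight[1] <- -defB$weight[1]
  zA <- standardize_prs(compute_prs(dos, defA))$z
  zB <- standardize_prs(compute_prs(dos, defB))$z
  expect_equal(zA, zB, tolerance = 1e-10)
})
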