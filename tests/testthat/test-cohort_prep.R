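make_samples <- function(n = 20) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             sex = rep(c("F", "M"), length.out = n),
             age = 60, call_rate = 0.99,
             het = rep(c(-0.5, 0.5), length.out = n),
             PC1 = rep(c(-1, 1), length.out = n),
             PC2 = rep(c(-1, 1), length.out = n),
             self_report_cancer = FALSE, death_cause_cancer = FALSE)
}

test_that("sample QC removes the documented failures", {
  ## n large enough that a single extreme value can exceed 5 within-cohort SD
  s <- make_samples(60)
  s$call_rate[1] <- 0.969          # below 97%
  s$het[2] <- 50                   # heterozygosity outlier
  s$PC2[3] <- 60                   # PC2 outlier
  qc <- sample_qc(s)
  expect_setequal(qc$removed$sample_id, c("S01", "S02", "S03"))
  expect_match(qc$removed$reason[qc$removed$sample_id == "S01"], "low_call_rate")
  expect_match(qc$removed$reason[qc$removed$sample_id == "S02"], "heterozygosity_outlier")
  expect_match(qc$removed$reason[qc$removed$sample_id == "S03"], "pc2_outlier")
  ## a sample at the mean is kept; boundary call rate 0.97 is kept
  expect_true("S04" %in% qc$kept$sample_id)
  s2 <- make_samples(); s2$call_rate[1] <- 0.97
  expect_equal(nrow(sample_qc(s2)$removed), 0L)
  ## missing metric handling is configurable
  s3 <- make_samples(); s3$call_rate[5] <- NA
  expect_true("S05" %in% sample_qc(s3, missing_metric = "drop")$removed$sample_id)
  expect_true("S05" %in% sample_qc(s3, missing_metric = "keep")$kept$sample_id)
})

test_that("first-primary rule drives case assignment; same-date ties count twice", {
  s <- make_samples(6)
  d <- data.frame(
    sample_id = c("S01", "S01", "S02", "S02", "S03"),
    site_code = c("lung", "colon", "lung", "colon", "colon"),
    date = as.Date(c("2010-05-01", "2013-02-01",   # lung first
                     "2010-05-01", "2010-05-01",   # tie: case for both
                     "2011-01-01")))
  lung <- assign_case_control(s, d, "lung")
  colon <- assign_case_control(s, d, "colon")
  expect_setequal(lung$cases, c("S01", "S02"))
  expect_setequal(colon$cases, c("S02", "S03"))    # S01's colon is second primary
  ## diagnosed samples are never controls, for any cancer
  expect_false(any(c("S01", "S02", "S03") %in% lung$controls))
  expect_setequal(lung$controls, c("S04", "S05", "S06"))
})

test_that("controls exclude self-reported and death-certificate cancer", {
  s <- make_samples(6)
  s$self_report_cancer[4] <- TRUE
  s$death_cause_cancer[5] <- TRUE
  d <- data.frame(sample_id = "S01", site_code = "lung",
                  date = as.Date("2010-01-01"))
  a <- assign_case_control(s, d, "lung")
  expect_setequal(a$controls, c("S02", "S03", "S06"))
})

test_that("sex-specific cancers restrict both case and control sets", {
  s <- make_samples(8)
  d <- data.frame(sample_id = c("S01", "S02"), site_code = "breast",
                  date = as.Date("2010-01-01"))
  a <- assign_case_control(s, d, "breast", sex_specific = c(breast = "F"))
  expect_true(all(s$sex[match(a$controls, s$sample_id)] == "F"))
  expect_setequal(a$cases, "S01")  # S02 is male
})

test_that("incident/prevalent split partitions cases; same-date is prevalent", {
  s <- make_samples(8)
  d <- data.frame(sample_id = c("S01", "S02", "S03"), site_code = "lung",
                  date = as.Date(c("2005-01-01", "2008-01-01", "2012-01-01")))
  spec <- as.Date("2008-01-01")
  all_c <- assign_case_control(s, d, "lung")
  inc <- assign_case_control(s, d, "lung", subset = "incident",
                             specimen_date = spec)
  prev <- assign_case_control(s, d, "lung", subset = "prevalent",
                              specimen_date = spec)
  expect_setequal(c(inc$cases, prev$cases), all_c$cases)
  expect_setequal(inc$cases, "S03")
  expect_setequal(prev$cases, c("S01", "S02"))   # collection-date tie -> prevalent
  expect_error(assign_case_control(s, d, "pancreas"), "valid codes")
})

test_that("secondary phenotype prep: log transforms, WHR, range censoring", {
  s <- data.frame(sample_id = c("A", "B", "C"),
                  crp = c(exp(1), -1, 2),
                  waist = c(80, 90, 100), hip = c(100, 100, 125),
                  hba1c = c(40, 35, 50))
  out <- prepare_secondary_phenotypes(s, ranges = list(hba1c = c(36, 45)))
  expect_equal(out$samples$crp[1], 1.0)               # ln e
  expect_true(is.na(out$samples$crp[2]))              # non-positive -> missing
  expect_equal(out$samples$whr, c(0.8, 0.9, 0.8))
  expect_true(is.na(out$samples$hba1c[2]))            # below reportable range
  expect_true(is.na(out$samples$hba1c[3]))
  expect_equal(out$samples$hba1c[1], log(40))
  acts <- out$log$action[out$log$sample_id == "B"]
  expect_true("nonpositive_set_missing" %in% acts)
})

test_that("control sets are identical across non-sex-specific cancers", {
  st <- tiny_study()
  co <- st$cohorts[[1]]
  kept <- sample_qc(co$samples)$kept
  a1 <- assign_case_control(kept, co$diagnoses, "lung")
  a2 <- assign_case_control(kept, co$diagnoses, "nhl")
  expect_setequal(a1$controls, a2$controls)
  expect_length(intersect(a1$cases, a1$controls), 0)
})
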