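test_that("config validation rejects degenerate worlds", {
  expect_error(sim_config(n_samples = 1), "n_samples")
  expect_error(sim_config(blocks = list(list(n_variants = 2L,
                                             freqs = c(0, 0.3), rho = 0.5))),
               "degenerate allele frequency")
  expect_error(sim_config(blocks = list(list(n_variants = 1L,
                                             freqs = 0.3, rho = 1.2))),
               "rho")
  expect_error(sim_config(planted_traps = c(bogus = 1L)), "unknown trap")
})

test_that("genotype generation is deterministic under the seed", {
  cfg <- tiny_config(n = 200L, seed = 7L)
  a <- simulate_genotypes(cfg, 1L)
  b <- simulate_genotypes(cfg, 1L)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_genotypes(cfg, 2L)
  expect_false(identical(a$dosages, c2$dosages))
})

test_that("cohort invariants hold: dosage range, manifest alignment", {
  co <- tiny_study()$cohorts[[1]]
  expect_true(all(co$dosages >= 0 & co$dosages <= 2))
  expect_identical(ncol(co$dosages), nrow(co$manifest))
  expect_identical(colnames(co$dosages), co$manifest$variant_id)
  expect_true(all(co$diagnoses$sample_id %in% co$samples$sample_id))
})

test_that("rho = 1 with equal frequencies gives identical haplotypes (r2 = 1)", {
  cfg <- sim_config(n_samples = 500L, seed = 3L,
                    blocks = list(list(n_variants = 2L, freqs = c(0.3, 0.3),
                                       rho = 1)),
                    cancers = list(list(site = "lung", theta = 0,
                                        alpha = qlogis(0.1), sex = "both")),
                    planted_traps = c(duplicate = 0L), planted_qc = c(low_call = 0L))
  co <- simulate_genotypes(cfg, 1L)
  d <- co$dosages[, co$manifest[co$manifest$role == "main", ][["variant_id"]]]
  expect_equal(pairwise_r2(d[, 1], d[, 2]), 1.0)
})

test_that("independent blocks have near-zero cross-block r2 and correct means", {
  cfg <- sim_config(n_samples = 10000L, seed = 5L,
                    blocks = list(list(n_variants = 2L, freqs = c(0.3, 0.3), rho = 0),
                                  list(n_variants = 2L, freqs = c(0.3, 0.3), rho = 0)),
                    cancers = list(list(site = "lung", theta = 0,
                                        alpha = qlogis(0.1), sex = "both")),
                    planted_traps = c(duplicate = 0L), planted_qc = c(low_call = 0L))
  co <- simulate_genotypes(cfg, 1L)
  main <- co$manifest[co$manifest$role == "main", ][["variant_id"]]
  d <- co$dosages[, main]
  cross <- c(pairwise_r2(d[, 1], d[, 3]), pairwise_r2(d[, 1], d[, 4]),
             pairwise_r2(d[, 2], d[, 3]), pairwise_r2(d[, 2], d[, 4]))
  expect_lt(mean(cross), 0.01)  # E[r2] ~ 1/n under independence
  ## mean dosage within 3 binomial standard errors of 2f
  se <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(d[, 1]) - 0.6), 3 * se)
})

test_that("realized within-block r2 increases monotonically with rho", {
  rhos <- c(0, 0.3, 0.6, 0.9, 1)
  r2s <- vapply(rhos, function(rho) {
    cfg <- sim_config(n_samples = 4000L, seed = 9L,
                      blocks = list(list(n_variants = 2L,
                                         freqs = c(0.3, 0.3), rho = rho)),
                      cancers = list(list(site = "lung", theta = 0,
                                          alpha = qlogis(0.1), sex = "both")),
                      planted_traps = c(duplicate = 0L),
                      planted_qc = c(low_call = 0L))
    co <- simulate_genotypes(cfg, 1L)
    main <- co$manifest[co$manifest$role == "main", ][["variant_id"]]
    pairwise_r2(co$dosages[, main[1]], co$dosages[, main[2]])
  }, numeric(1))
  expect_true(all(diff(r2s) > 0))
  expect_equal(r2s[1], 0, tolerance = 0.01)
  expect_equal(r2s[5], 1)
})

test_that("baseline prevalence matches the logistic intercept when theta = 0", {
  cfg <- sim_config(n_samples = 20000L, seed = 13L,
                    cancers = list(list(site = "lung", theta = 0,
                                        alpha = qlogis(0.10), sex = "both")),
                    covariate_effects = c(age = 0, sex = 0),
                    secondary_traits = list(),
                    planted_qc = c(self_report = 0L))
  co <- simulate_genotypes(cfg, 1L)
  defs <- true_prs_definitions(co$manifest, cfg)
  co <- simulate_phenotypes(co, defs, cfg)
  prev <- length(unique(co$diagnoses$sample_id)) / nrow(co$samples)
  expect_lt(abs(prev - 0.10), 3 * sqrt(0.1 * 0.9 / 20000))
})

test_that("null PRS effect gives nominal type-I error across replicates", {
  ## 300 small replicates of the generative model + adjusted logistic refit
  hits <- 0L; n_rep <- 300L
  cfg0 <- sim_config(n_samples = 600L,
                     blocks = list(list(n_variants = 2L,
                                        freqs = c(0.3, 0.3), rho = 0)),
                     cancers = list(list(site = "lung", theta = 0,
                                         alpha = qlogis(0.15), sex = "both")),
                     secondary_traits = list(),
                     planted_traps = c(duplicate = 0L),
                     planted_qc = c(low_call = 0L, self_report = 0L))
  for (r in seq_len(n_rep)) {
    cfg <- cfg0; cfg$seed <- 1000L + r
    co <- simulate_genotypes(cfg, 1L)
    defs <- true_prs_definitions(co$manifest, cfg)
    co <- simulate_phenotypes(co, defs, cfg)
    z <- standardize_prs(compute_prs(co$dosages, defs$lung))$z
    d <- data.frame(co$samples,
                    y = as.integer(co$samples$sample_id %in% co$diagnoses$sample_id),
                    z = z)
    f <- fit_logistic(d, "y", "z", c("age", "sex"))
    hits <- hits + (f$p < 0.05)
  }
  rate <- hits / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("planted per-SD log OR is recovered within its confidence interval", {
  cfg <- sim_config(n_samples = 20000L, seed = 17L,
                    cancers = list(list(site = "lung", theta = log(1.3),
                                        alpha = qlogis(0.08), sex = "both")),
                    secondary_traits = list())
  co <- simulate_genotypes(cfg, 1L)
  defs <- true_prs_definitions(co$manifest, cfg)
  co <- simulate_phenotypes(co, defs, cfg)
  z <- standardize_prs(compute_prs(co$dosages, defs$lung))$z
  d <- data.frame(co$samples,
                  y = as.integer(co$samples$sample_id %in% co$diagnoses$sample_id),
                  z = z)
  f <- fit_logistic(d, "y", "z", covars())
  expect_lt(abs(f$beta - log(1.3)), 1.96 * f$se)
})

test_that("secondary traits recover planted slopes; zero noise is exact", {
  st <- tiny_study()
  cfg <- st$config
  co <- st$cohorts[[1]]
  z <- standardize_prs(compute_prs(co$dosages, st$true_prs$lung))$z
  d <- data.frame(co$samples, z = z)
  f_bmi <- fit_linear(d, "bmi", "z")
  expect_lt(abs(f_bmi$beta - 0.1), 1.96 * f_bmi$se)
  ## exact recovery when noise_sd = 0
  cfg0 <- tiny_config(n = 300L, seed = 23L,
                      secondary_traits = list(list(name = "pure", cancer = "lung",
                                                   slope = 0.37, noise_sd = 0)))
  co0 <- simulate_genotypes(cfg0, 1L)
  defs0 <- true_prs_definitions(co0$manifest, cfg0)
  co0 <- simulate_secondary_traits(co0, defs0, cfg0)
  z0 <- standardize_prs(compute_prs(co0$dosages, defs0$lung))$z
  f0 <- fit_linear(data.frame(co0$samples, z = z0), "pure", "z")
  expect_equal(f0$beta, 0.37, tolerance = 1e-10)
})

test_that("catalog traps are planted as recorded in the trap manifest", {
  st <- tiny_study()
  tr <- st$traps
  ## duplicates share key with a smaller-p main record
  for (rid in tr[tr$trap_type == "duplicate", ][["record_id"]]) {
    dup <- st$catalog[st$catalog$record_id == rid, ]
    twin <- st$catalog[st$catalog$rsid == dup$rsid &
                         st$catalog$record_id != rid &
                         st$catalog$phenotype == dup$phenotype, ]
    expect_true(all(twin$p_value < dup$p_value))
  }
  ## ambiguous traps sit on A/T panel variants at MAF 0.47
  amb <- st$manifest[st$manifest$role == "trap_ambiguous", ]
  expect_true(all(amb$ref == "A" & amb$alt == "T" & amb$freq == 0.47))
  ## proxy-only leads are absent from the panel but linked in the LD table
  for (rid in tr[tr$trap_type == "proxy_only", ][["record_id"]]) {
    lead <- st$catalog[st$catalog$record_id == rid, ][["rsid"]]
    expect_false(lead %in% st$manifest$variant_id)
    expect_true(lead %in% st$ld$var1)
    expect_gte(st$ld[st$ld$var1 == lead, ][["r2"]], 0.8)
  }
})
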