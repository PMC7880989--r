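## Shared fixtures: one small simulated study reused across test files
## (memoized — generation is deterministic under the fixed seed).

.fixture_env <- new.env(parent = emptyenv())

tiny_config <- function(n = 800L, seed = 42L, ...) {
  sim_config(n_samples = n, seed = seed, ...)
}

tiny_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulate_study(tiny_config())
  .fixture_env$study
}

## QC-passed dosage matrix for one cohort of the shared study
tiny_dosages <- function(study = tiny_study(), cohort = 1L) {
  key <- paste0("dos", cohort)
  if (is.null(.fixture_env[[key]])) {
    co <- study$cohorts[[cohort]]
    qc <- sample_qc(co$samples)
    .fixture_env[[key]] <- co$dosages[rownames(co$dosages) %in% qc$kept$sample_id, ]
  }
  .fixture_env[[key]]
}

## standard covariate columns used across association tests
covars <- function() c("age", "sex", paste0("PC", 1:10), "batch")

## random non-degenerate 2x2 case-control table as a long data.frame
random_2x2 <- function() {
  repeat {
    n <- sample(5:40, 4, replace = TRUE)  # a,b,c,d all >= 5
    if (all(n >= 5)) break
  }
  data.frame(
    y = rep(c(1, 1, 0, 0), n),
    x = rep(c(1, 0, 1, 0), n))
}

## brute-force BH step-up oracle (independent of bh_fdr)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[o[i]] <- min(1, min(p[o[seq(i, m)]] * m / seq(i, m)))
  q
}

## sequential priority-respecting pruning oracle (independent code path):
## scan candidates in priority order, keep iff compatible with all kept
prune_oracle <- function(cand, ld_mat, r2_max = 0.3) {
  ord <- order(cand$breadth, cand$p, -ifelse(is.na(cand$info), -Inf, cand$info),
               cand$variant_id)
  kept <- character()
  for (i in ord) {
    v <- cand$variant_id[i]
    ok <- TRUE
    for (u in kept) {
      r2 <- ld_mat[v, u]
      if (!is.na(r2) && r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, v)
  }
  kept
}
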