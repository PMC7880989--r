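test_that("pairwise r2 matches hand-computed Pearson values", {
  expect_equal(pairwise_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1.0)
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0.0)
  ## brute-force Pearson by hand: cor((0,1,2,0),(0,1,2,2))^2 = 0.2066...
  expect_equal(pairwise_r2(c(0, 1, 2, 0), c(0, 1, 2, 2)), 0.2066116,
               tolerance = 1e-6)
  ## undefined cases
  expect_true(is.na(pairwise_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_true(is.na(pairwise_r2(c(0, NA, NA), c(0, 1, 2))))
  ## missing values: computed over shared non-missing samples
  expect_equal(pairwise_r2(c(0, 1, 2, NA, 0), c(0, 1, 2, 2, NA)), 1.0)
})

cand_dt <- function(ids, p, info = rep(0.95, length(ids)),
                    breadth = rep(0L, length(ids))) {
  data.frame(variant_id = ids, p = p, info = info, breadth = breadth,
             chrom = rep("1", length(ids)))
}

ld_mat <- function(ids, pairs) {
  m <- diag(length(ids)); dimnames(m) <- list(ids, ids)
  for (pr in pairs) { m[pr[[1]], pr[[2]]] <- pr[[3]]; m[pr[[2]], pr[[1]]] <- pr[[3]] }
  m
}

test_that("priority pruning resolves conflicts by smallest p", {
  ld <- ld_mat(c("A", "B"), list(list("A", "B", 0.5)))
  out <- priority_prune(cand_dt(c("A", "B"), c(1e-10, 1e-8)), ld)
  expect_equal(out$kept, "A")
  expect_equal(out$report$removed_by[out$report$variant_id == "B"], "A")
  ## both kept below threshold
  ld2 <- ld_mat(c("A", "B"), list(list("A", "B", 0.2)))
  expect_setequal(priority_prune(cand_dt(c("A", "B"), c(1e-10, 1e-8)), ld2)$kept,
                  c("A", "B"))
  ## chain A-B 0.5, B-C 0.5, A-C 0.1 with p_A < p_B < p_C -> {A, C}
  ld3 <- ld_mat(c("A", "B", "C"), list(list("A", "B", 0.5),
                                       list("B", "C", 0.5),
                                       list("A", "C", 0.1)))
  out3 <- priority_prune(cand_dt(c("A", "B", "C"), c(1e-12, 1e-10, 1e-8)), ld3)
  expect_equal(sort(out3$kept), c("A", "C"))
})

test_that("priority order: breadth, then p, then imputation info", {
  ld <- ld_mat(c("A", "B"), list(list("A", "B", 0.9)))
  ## broader phenotype wins despite larger p
  out <- priority_prune(cand_dt(c("A", "B"), c(1e-8, 1e-12),
                                breadth = c(0L, 1L)), ld)
  expect_equal(out$kept, "A")
  ## equal p: higher info wins
  out2 <- priority_prune(cand_dt(c("A", "B"), c(1e-8, 1e-8),
                                 info = c(0.90, 0.99)), ld)
  expect_equal(out2$kept, "B")
  ## empty input warns and returns empty
  expect_warning(out3 <- priority_prune(cand_dt(character(), numeric()), ld),
                 "empty")
  expect_length(out3$kept, 0)
})

test_that("pairs without LD info are treated independent; cross-chrom skipped", {
  cand <- data.frame(variant_id = c("A", "B", "C", "D"),
                     p = c(1e-10, 1e-9, 1e-8, 1e-7),
                     info = 0.9, breadth = 0L, chrom = c("1", "1", "1", "2"))
  ld <- ld_mat(c("A", "B"), list(list("A", "B", 0.9)))  # C, D absent
  out <- priority_prune(cand, ld)
  expect_setequal(out$kept, c("A", "C", "D"))  # C: no LD info; D: cross-chrom
  expect_match(out$report$note[out$report$variant_id == "C"], "assumed independent")
  expect_true(is.na(out$report$note[out$report$variant_id == "D"]))
})

test_that("greedy pruning agrees with the sequential oracle on random instances", {
  set.seed(202)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    ids <- sprintf("V%02d", seq_len(n))
    cand <- data.frame(variant_id = ids,
                       p = 10^-runif(n, 8, 20),
                       info = round(runif(n, 0.7, 1), 3),
                       breadth = sample(0:1, n, replace = TRUE),
                       chrom = rep("1", n))
    m <- diag(n); dimnames(m) <- list(ids, ids)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      r2 <- ifelse(runif(1) < 0.4, runif(1), 0)
      m[i, j] <- m[j, i] <- r2
    }
    expect_identical(priority_prune(cand, m)$kept, prune_oracle(cand, m))
  }
})

test_that("kept sets satisfy the pairwise r2 bound and monotonicity in r2_max", {
  st <- tiny_study()
  dos <- tiny_dosages(st, 1L)
  ids <- st$manifest[st$manifest$role == "main", ][["variant_id"]]
  ld <- ld_from_dosages(dos, ids)
  cand <- data.frame(variant_id = ids, p = 10^-seq(8, 8 + length(ids) - 1),
                     info = 0.9, breadth = 0L,
                     chrom = st$manifest$chrom[match(ids, st$manifest$variant_id)])
  kept_03 <- priority_prune(cand, ld, r2_max = 0.3)$kept
  off <- ld[kept_03, kept_03]; diag(off) <- 0
  same_chrom <- outer(cand$chrom[match(kept_03, cand$variant_id)],
                      cand$chrom[match(kept_03, cand$variant_id)], "==")
  expect_true(all(off[same_chrom] < 0.3))
  for (r2max in c(0.5, 0.8, 1.0)) {
    kept_hi <- priority_prune(cand, ld, r2_max = r2max)$kept
    expect_true(all(kept_03 %in% kept_hi))
  }
})
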