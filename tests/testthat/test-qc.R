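test_that("HWE chi-square test matches an independently coded oracle", {
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_lt(hwe_test(50, 0, 50), 1e-10)

  # direct chi-square computation, coded from the definition
  oracle <- function(aa, ab, bb) {
    n <- aa + ab + bb
    p <- (2 * aa + ab) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    pchisq(sum((c(aa, ab, bb) - e)^2 / e), df = 1, lower.tail = FALSE)
  }
  expect_equal(hwe_test(30, 40, 30), oracle(30, 40, 30), tolerance = 1e-6)
  expect_equal(hwe_test(10, 70, 20), oracle(10, 70, 20), tolerance = 1e-6)

  expect_error(hwe_test(-1, 2, 3), "non-negative")
  expect_error(hwe_test(0, 0, 0), "positive")
})

test_that("QC filters remove the right variants and samples", {
  g <- simulate_genotypes(100, 40, maf_range = c(0.2, 0.5), seed = 1)
  clean <- qc_filter(g)
  expect_identical(dim(clean$genotypes$dosage), dim(g$dosage))
  expect_true(all(clean$report$removed == 0))

  # toy fixture: 6 samples x 4 SNPs
  dos <- rbind(c(1L, 0L, 1L, 2L),
               c(1L, 0L, NA, 1L),
               c(0L, 0L, NA, 1L),
               c(2L, 0L, 1L, 0L),
               c(NA, NA, NA, NA),   # sample at 75%+ missingness
               c(1L, 0L, NA, 2L))
  dimnames(dos) <- list(paste0("s", 1:6), paste0("v", 1:4))
  toy <- structure(list(
    dosage = dos,
    map = data.frame(chr = 1L, id = paste0("v", 1:4), pos = 1:4 * 100L,
                     a1 = "A", a2 = "G"),
    freqs = colMeans(dos, na.rm = TRUE) / 2), class = "genotype_matrix")
  # v2 is monomorphic (fails MAF), v3 is >50% missing, sample s5 is all-NA
  res <- qc_filter(toy, maf_min = 0.01, hwe_p_min = 1e-4,
                   var_miss_max = 0.5, sample_miss_max = 0.5)
  expect_identical(colnames(res$genotypes$dosage), c("v1", "v4"))
  expect_identical(rownames(res$genotypes$dosage),
                   paste0("s", c(1:4, 6)))
  expect_identical(unname(res$report$removed[["maf"]]), 1L)
  expect_identical(unname(res$report$removed[["var_missingness"]]), 1L)
  expect_identical(unname(res$report$removed[["sample_missingness"]]), 1L)
  # removals account for the size change
  expect_identical(res$report$variants_in - res$report$variants_out,
                   sum(res$report$removed[c("maf", "hwe",
                                            "var_missingness")]))

  expect_error(qc_filter(g, maf_min = 0.6), "maf_min")
})

test_that("QC filtering is idempotent", {
  g <- simulate_genotypes(80, 60, maf_range = c(0.01, 0.5),
                          missing_rate = 0.01, seed = 2)
  once <- qc_filter(g)
  twice <- qc_filter(once$genotypes)
  expect_identical(once$genotypes$dosage, twice$genotypes$dosage)
  expect_true(all(twice$report$removed == 0))
})

test_that("an all-failing panel warns rather than errors", {
  dos <- matrix(2L, 4, 3, dimnames = list(paste0("s", 1:4),
                                          paste0("v", 1:3)))
  mono <- structure(list(
    dosage = dos,
    map = data.frame(chr = 1L, id = colnames(dos), pos = 1:3,
                     a1 = "A", a2 = "G"),
    freqs = rep(1, 3)), class = "genotype_matrix")
  expect_warning(res <- qc_filter(mono), "all variants removed")
  expect_true(res$report$empty)
})

test_that("relatedness pruning removes conflicts greedily", {
  # all unrelated: everyone retained
  g <- simulate_genotypes(15, 400, seed = 3)
  A <- compute_grm(g)
  off <- A$values; diag(off) <- 0
  thr <- max(off) + 0.01
  expect_identical(prune_related(A, thr), A$samples)

  # a duplicated individual: exactly one of the pair removed
  dup <- A
  dup$values[1, 2] <- dup$values[2, 1] <- 0.98
  kept <- prune_related(dup, thr)
  expect_identical(length(kept), length(A$samples) - 1L)
  expect_true(sum(c(A$samples[1], A$samples[2]) %in% kept) == 1L)
})

test_that("pruning leaves no pair above threshold and matches brute force", {
  set.seed(4)
  n <- 30
  V <- matrix(0, n, n)
  conflicts <- cbind(sample(n, 10), sample(n, 10))
  conflicts <- conflicts[conflicts[, 1] != conflicts[, 2], , drop = FALSE]
  V[conflicts] <- 0.4
  V <- pmax(V, t(V)); diag(V) <- 1
  A <- as_grm(V, samples = sprintf("p%02d", 1:n))
  kept <- prune_related(A, 0.05)
  sub <- V[match(kept, A$samples), match(kept, A$samples)]
  diag(sub) <- 0
  expect_true(all(sub <= 0.05))

  # independent greedy re-implementation for the retained-set size
  greedy <- function(M, ids, thr) {
    adj <- M > thr; diag(adj) <- FALSE
    act <- rep(TRUE, nrow(M))
    repeat {
      deg <- rowSums(adj[, act, drop = FALSE]) * act
      if (max(deg) == 0) break
      cand <- which(deg == max(deg))
      act[cand[order(ids[cand])][length(cand)]] <- FALSE
    }
    ids[act]
  }
  expect_identical(kept, greedy(V, A$samples, 0.05))
})
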