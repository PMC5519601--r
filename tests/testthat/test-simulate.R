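test_that("simulated dosages are binomial with the drawn frequencies", {
  g <- simulate_genotypes(10000, 1, maf_range = c(0.5, 0.5), seed = 1)
  se <- sqrt(2 * 0.25 / 10000)
  expect_lt(abs(mean(g$dosage) - 1), 4 * se)

  g2 <- simulate_genotypes(2000, 500, maf_range = c(0.05, 0.5), seed = 2)
  emp <- colMeans(g2$dosage) / 2
  # 99.9% binomial band around each drawn p
  half <- qnorm(0.9995) * sqrt(g2$freqs * (1 - g2$freqs) / (2 * 2000))
  inside <- abs(emp - g2$freqs) <= half
  expect_gte(mean(inside), 0.99)
})

test_that("genotype simulation validates inputs and is reproducible", {
  expect_error(simulate_genotypes(0, 10), "positive")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.2, 0.7)),
               "maf_range")
  expect_error(simulate_genotypes(10, 10, missing_rate = 1), "missing_rate")
  a <- simulate_genotypes(50, 30, missing_rate = 0.05, seed = 9)
  b <- simulate_genotypes(50, 30, missing_rate = 0.05, seed = 9)
  expect_identical(a, b)
})

test_that("zero genetic variance yields phenotypes unlinked to genotype", {
  g <- simulate_genotypes(800, 300, seed = 3)
  coh <- simulate_gxe_cohort(g, c(400, 400), matrix(0, 2, 2), c(1, 1),
                             covariates = NULL, seed = 4)
  # score individuals with random SNP weights; no association expected
  w <- gxegreml:::.standardize_dosage(g$dosage[1:800, ])$w
  score <- w %*% rnorm(300)
  expect_lt(abs(cor(coh$phenotype, score)), 4 / sqrt(800))
  expect_true(all(abs(coh$g_true) < 1e-12))
})

test_that("realized per-group heritability and effect correlation are unbiased", {
  h2 <- c(0.2, 0.2); rg <- 0.6
  sg <- matrix(c(h2[1], rg * sqrt(prod(h2)), rg * sqrt(prod(h2)), h2[2]), 2)
  reps <- 30
  h2_real <- matrix(NA_real_, reps, 2)
  rg_real <- numeric(reps)
  for (b in seq_len(reps)) {
    g <- simulate_genotypes(2000, 2000, seed = 100 + b)
    coh <- simulate_gxe_cohort(g, c(1000, 1000), sg, 1 - h2,
                               covariates = NULL, seed = 200 + b)
    for (k in 1:2) {
      rows <- coh$group == levels(coh$group)[k]
      h2_real[b, k] <- var(coh$g_true[rows]) / var(coh$phenotype[rows])
    }
    B <- attr(coh, "effects")
    rg_real[b] <- cor(B[, 1], B[, 2])
  }
  for (k in 1:2) {
    mc_se <- sd(h2_real[, k]) / sqrt(reps)
    expect_lt(abs(mean(h2_real[, k]) - h2[k]), 3 * mc_se)
  }
  expect_lt(abs(mean(rg_real) - rg), 3 * sd(rg_real) / sqrt(reps))
})

test_that("group sizes are honoured exactly in a four-group design", {
  # 1/10-scale group proportions of a large cognitive-trait cohort
  sizes <- c(1320, 531, 436, 257)
  g <- simulate_genotypes(sum(sizes), 50, seed = 5)
  sg <- diag(0.1, 4)
  coh <- simulate_gxe_cohort(g, sizes, sg, rep(0.9, 4), seed = 6)
  expect_identical(as.integer(table(coh$group)), as.integer(sizes))
  expect_identical(levels(coh$group), c("B&NS", "B&S", "NB&NS", "NB&S"))
  expect_true(all(coh$breastfed[coh$group == "B&S"] == "yes"))
  expect_true(all(coh$maternal_smoking[coh$group == "NB&NS"] == "no"))
})

test_that("cohort simulation validates its covariance inputs", {
  g <- simulate_genotypes(100, 20, seed = 7)
  bad <- matrix(c(0.2, 0.5, 0.5, 0.2), 2)  # correlation > 1: not PSD
  expect_error(simulate_gxe_cohort(g, c(50, 50), bad, c(1, 1)),
               "positive semidefinite")
  expect_error(
    simulate_gxe_cohort(g, c(80, 80), diag(0.1, 2), c(1, 1)),
    "exceed")
})

test_that("truncation selection retains the configured region", {
  g <- simulate_genotypes(1000, 50, seed = 8)
  coh <- simulate_gxe_cohort(g, 1000, matrix(0.2), 0.8,
                             covariates = NULL, seed = 9)

  all_kept <- apply_selection(coh, selection_regime(-Inf, Inf, h2 = 0.2))
  expect_equal(nrow(all_kept), nrow(coh))

  set.seed(10)
  big <- data.frame(phenotype = rnorm(1e5))
  sel <- apply_selection(big, selection_regime(-1, 1, h2 = 0.2))
  p_true <- pnorm(1) - pnorm(-1)
  se <- sqrt(p_true * (1 - p_true) / 1e5)
  expect_lt(abs(attr(sel, "realized_proportion") - p_true), 3 * se)

  # independent selection variable leaves the phenotype mean untouched
  sel0 <- apply_selection(big, selection_regime(0.5, Inf, h2 = 0.2, r = 0),
                          seed = 11)
  expect_lt(abs(mean(sel0$phenotype)), 4 / sqrt(nrow(sel0)))

  expect_error(apply_selection(big, selection_regime(30, 31, h2 = 0.2)),
               "no individuals")
})
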