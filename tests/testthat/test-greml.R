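test_that("AI-REML matches direct restricted-likelihood maximization", {
  d <- sim_gxe_data(50, 100, h2 = 0.5, rg = 0, seed = 5)
  fit <- greml_fit(d$cohort$phenotype, d$cohort$group, d$grm,
                   ids = d$cohort$sample_id)
  blk <- as.integer(factor(d$cohort$group))
  orc <- oracle_reml_fit(d$cohort$phenotype, blk, d$grm$values)
  expect_lt(abs(fit$logL - orc$logL), 1e-6)
  expect_lt(max(abs(fit$theta - orc$theta)), 1e-3)
  # the package's reported likelihood is the true restricted likelihood
  expect_equal(oracle_reml_logL(fit$theta, d$cohort$phenotype, blk,
                                d$grm$values),
               fit$logL, tolerance = 1e-8)
})

test_that("bivariate AI-REML agrees with the direct oracle", {
  d <- sim_gxe_data(c(60, 60), 80, h2 = c(0.4, 0.4), rg = 0.5, seed = 7)
  fit <- greml_fit(d$cohort$phenotype, d$cohort$group, d$grm,
                   ids = d$cohort$sample_id)
  orc <- oracle_reml_fit(d$cohort$phenotype,
                         as.integer(factor(d$cohort$group)), d$grm$values)
  expect_lt(abs(fit$logL - orc$logL), 1e-6)
  expect_lt(max(abs(fit$theta - orc$theta)), 1e-3)
})

test_that("the likelihood trail is monotone non-decreasing", {
  d <- sim_gxe_data(c(100, 100), 150, h2 = c(0.3, 0.3), rg = 0.8, seed = 11)
  fit <- greml_fit(d$cohort$phenotype, d$cohort$group, d$grm,
                   ids = d$cohort$sample_id)
  expect_true(all(diff(fit$logL_trail) >= -1e-9))
  expect_true(fit$converged)
})

test_that("an identity-like GRM is flagged non-identifiable", {
  set.seed(12)
  n <- 60
  A <- as_grm(diag(n), samples = sprintf("s%02d", 1:n))
  y <- rnorm(n)
  fit <- greml_fit(y, rep("G1", n), A, ids = A$samples)
  expect_false(fit$identifiable)
  expect_true(all(is.na(fit$vcov)))
  expect_error(suppressWarnings(genetic_correlation(fit, 1, 2)))
})

test_that("location and scale changes transform components as they must", {
  d <- sim_gxe_data(c(80, 80), 100, h2 = c(0.3, 0.3), rg = 0.6, seed = 13)
  y <- d$cohort$phenotype
  f1 <- greml_fit(y, d$cohort$group, d$grm, ids = d$cohort$sample_id)
  f2 <- greml_fit(3 * y + 7, d$cohort$group, d$grm,
                  ids = d$cohort$sample_id)
  expect_equal(f2$theta, 9 * f1$theta, tolerance = 1e-4)
  r1 <- genetic_correlation(f1, 1, 2)
  r2 <- genetic_correlation(f2, 1, 2)
  expect_equal(r1$r_g, r2$r_g, tolerance = 1e-4)
})

test_that("multi-trait mode with disjoint blocks reproduces the GxE mode", {
  d <- sim_gxe_data(c(70, 70), 90, h2 = c(0.4, 0.4), rg = 0.7, seed = 14)
  fa <- greml_fit(d$cohort$phenotype, d$cohort$group, d$grm,
                  ids = d$cohort$sample_id, mode = "gxe")
  fb <- greml_fit(d$cohort$phenotype, d$cohort$group, d$grm,
                  ids = d$cohort$sample_id, mode = "multi_trait")
  # no shared individuals: the residual covariance drops out and the two
  # parameterizations coincide
  expect_equal(fa$theta, fb$theta, tolerance = 1e-10)
  expect_equal(fa$logL, fb$logL, tolerance = 1e-10)
})

test_that("multi-trait mode estimates residual covariance on shared samples", {
  set.seed(15)
  n <- 250; m <- 300
  g <- simulate_genotypes(n, m, seed = 16)
  std <- gxegreml:::.standardize_dosage(g$dosage)$w
  bet <- rnorm(m, sd = sqrt(0.4 / m))
  gv <- drop(std %*% bet)
  e1 <- rnorm(n, sd = sqrt(0.6))
  e2 <- 0.5 * e1 + rnorm(n, sd = sqrt(0.6 - 0.25 * 0.6))
  y <- c(gv + e1, gv + e2)   # two traits, same genetics, correlated residual
  ids <- rep(rownames(g$dosage), 2)
  blocks <- rep(c("t1", "t2"), each = n)
  A <- compute_grm(g)
  fit <- greml_fit(y, blocks, A, ids = ids, mode = "multi_trait")
  pt <- fit$param_table
  k_ecov <- which(pt$type == "e" & pt$i != pt$j)
  expect_length(k_ecov, 1L)
  expect_gt(fit$theta[k_ecov], 0.05)  # true residual covariance is 0.3
  rg <- genetic_correlation(fit, 1, 2)
  expect_lt(abs(rg$r_g - 1), 3 * rg$se + 0.1)
})

test_that("non-convergence raises a diagnostic error with the trail", {
  d <- sim_gxe_data(c(40, 40), 60, h2 = c(0.3, 0.3), rg = 0.5, seed = 17)
  err <- tryCatch(
    greml_fit(d$cohort$phenotype, d$cohort$group, d$grm,
              ids = d$cohort$sample_id, max_iter = 1L, tol = 1e-12),
    greml_convergence_error = function(e) e)
  expect_s3_class(err, "greml_convergence_error")
  expect_true(length(err$trail) >= 1)
})

test_that("input validation catches malformed designs", {
  d <- sim_gxe_data(c(30, 30), 40, h2 = c(0.2, 0.2), rg = 1, seed = 18)
  coh <- d$cohort
  expect_error(greml_fit(coh$phenotype, coh$group, d$grm,
                         ids = rep(coh$sample_id[1], nrow(coh))),
               "duplicate")
  expect_error(greml_fit(coh$phenotype, coh$group, d$grm,
                         ids = paste0("zz", seq_len(nrow(coh)))),
               "absent")
  expect_error(greml_fit(coh$phenotype[1:10], coh$group, d$grm,
                         ids = coh$sample_id), "differ")
})

test_that("observed-information option yields comparable standard errors", {
  d <- sim_gxe_data(c(80, 80), 100, h2 = c(0.4, 0.4), rg = 0.8, seed = 19)
  fa <- greml_fit(d$cohort$phenotype, d$cohort$group, d$grm,
                  ids = d$cohort$sample_id, info_type = "average")
  fo <- greml_fit(d$cohort$phenotype, d$cohort$group, d$grm,
                  ids = d$cohort$sample_id, info_type = "observed")
  expect_equal(fa$theta, fo$theta, tolerance = 1e-8)
  sa <- sqrt(diag(fa$vcov)); so <- sqrt(diag(fo$vcov))
  expect_true(all(so / sa > 0.5 & so / sa < 2))
})
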