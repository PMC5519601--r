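test_that("truncation constants match the normal pdf/cdf and their limits", {
  tc <- truncation_constants(0, 1)
  expect_equal(tc$K1, 0.5)
  expect_equal(tc$i1, dnorm(0) / 0.5, tolerance = 1e-12)
  expect_equal(tc$K2, pnorm(1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(tc$i2, dnorm(1) / pnorm(1, lower.tail = FALSE),
               tolerance = 1e-12)

  lim <- truncation_constants(-Inf, Inf)
  expect_equal(lim$K1, 1)
  expect_equal(lim$K2, 0)
  expect_equal(lim$K1 * lim$i1, 0)

  expect_error(truncation_constants(1, 1), "t1 < t2")
  expect_error(selection_regime(2, 1, h2 = 0.5), "t1 < t2")
  expect_error(selection_regime(-1, 1, h2 = 1.5), "h2")
})

test_that("no-selection limit recovers the unselected moments", {
  m <- post_selection_moments(selection_regime(-Inf, Inf, h2 = 0.37))
  expect_equal(m$mean_y, 0)
  expect_equal(m$var_y, 1)
  expect_equal(m$var_g, 0.37)
  expect_equal(m$h2_s, 0.37)
  expect_equal(m$b, 1)
})

test_that("selected-phenotype variance equals the textbook truncated normal", {
  grid <- expand.grid(t1 = c(-Inf, -1.5, -0.5, 0), t2 = c(0.5, 1, 2, Inf))
  grid <- grid[grid$t1 < grid$t2, ]
  for (r in seq_len(nrow(grid))) {
    t1 <- grid$t1[r]; t2 <- grid$t2[r]
    m <- post_selection_moments(selection_regime(t1, t2, h2 = 0.3))
    xphi <- function(t) if (is.finite(t)) t * dnorm(t) else 0
    Z <- pnorm(t2) - pnorm(t1)
    ref_var <- 1 + (xphi(t1) - xphi(t2)) / Z - m$mean_y^2
    expect_equal(m$var_y, ref_var, tolerance = 1e-12)
  }
})

test_that("direct-selection moments match a Monte-Carlo oracle", {
  set.seed(42)
  n <- 4e5
  h2 <- 0.5
  g <- rnorm(n, sd = sqrt(h2))
  y <- g + rnorm(n, sd = sqrt(1 - h2))
  keep <- y > -1 & y < 1
  m <- post_selection_moments(selection_regime(-1, 1, h2 = h2))
  ns <- sum(keep)
  mc_se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(y[keep]) - m$mean_y), 4 * mc_se(y[keep]))
  expect_lt(abs(mean(g[keep]) - m$mean_g), 4 * mc_se(g[keep]))
  expect_lt(abs(var(y[keep]) - m$var_y), 4 * var(y[keep]) * sqrt(2 / ns))
  expect_lt(abs(var(g[keep]) - m$var_g), 4 * var(g[keep]) * sqrt(2 / ns))
  # realized heritability of the selected subset
  expect_lt(abs(var(g[keep]) / var(y[keep]) - m$h2_s), 0.02)
})

test_that("correlated-variable selection matches a bivariate MC oracle", {
  set.seed(43)
  n <- 4e5
  h2 <- 0.3; r <- 0.6
  g <- rnorm(n, sd = sqrt(h2))
  y <- g + rnorm(n, sd = sqrt(1 - h2))
  yE <- r * y + sqrt(1 - r^2) * rnorm(n)
  keep <- yE > -0.5 & yE < 1.5
  m <- correlated_selection_moments(selection_regime(-0.5, 1.5,
                                                     h2 = h2, r = r))
  ns <- sum(keep)
  mc_se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(y[keep]) - m$mean_y), 4 * mc_se(y[keep]))
  expect_lt(abs(var(y[keep]) - m$var_y), 4 * var(y[keep]) * sqrt(2 / ns))
  expect_lt(abs(mean(g[keep]) - m$mean_g), 4 * mc_se(g[keep]))
  expect_lt(abs(var(g[keep]) - m$var_g), 4 * var(g[keep]) * sqrt(2 / ns))
  expect_lt(abs(mean(g[keep]^2) - m$e_g2), 4 * mc_se(g[keep]^2))
})

test_that("r = 0 and r = 1 limits of the correlated case behave", {
  h2 <- 0.4
  m0 <- correlated_selection_moments(selection_regime(-1, 0.5, h2 = h2,
                                                      r = 0))
  expect_equal(m0$mean_y, 0)
  expect_equal(m0$var_y, 1)
  expect_equal(m0$h2_s, h2)

  m1 <- correlated_selection_moments(selection_regime(-1, 0.5, h2 = h2,
                                                      r = 1))
  d <- post_selection_moments(selection_regime(-1, 0.5, h2 = h2))
  expect_equal(m1$mean_y, d$mean_y, tolerance = 1e-12)
  expect_equal(m1$var_g, d$var_g, tolerance = 1e-12)
  expect_equal(m1$b, d$b, tolerance = 1e-12)
  # the zero-mean variant differs from the exact one precisely by E(g_s)^2
  expect_equal(m1$var_g_printed - m1$var_g, m1$mean_g^2, tolerance = 1e-12)
  # and coincides with it for an interval symmetric about zero
  ms <- correlated_selection_moments(selection_regime(-1, 1, h2 = h2,
                                                      r = 0.7))
  expect_equal(ms$var_g_printed, ms$var_g, tolerance = 1e-12)
})

test_that("interval selection shrinks genetic variance but not the variance ratio", {
  grid <- expand.grid(t1 = c(-2, -1, 0), t2 = c(0.5, 1.5, 2.5),
                      h2 = c(0.1, 0.5, 0.9))
  grid <- grid[grid$t1 < grid$t2, ]
  for (r in seq_len(nrow(grid))) {
    m <- post_selection_moments(
      selection_regime(grid$t1[r], grid$t2[r], h2 = grid$h2[r]))
    # genetic variance is reduced (b <= 1) ...
    expect_lte(m$var_g, grid$h2[r] + 1e-12)
    expect_lte(m$b, 1 + 1e-12)
    expect_gte(m$b, 0)
    # ... but phenotypic variance is reduced more, so the post-selection
    # variance ratio is at least h2 (negative g-e correlation in survivors)
    expect_gte(m$h2_s, grid$h2[r] - 1e-12)
  }
})

test_that("moments approach the no-selection limit continuously", {
  h2 <- 0.3
  wide <- post_selection_moments(selection_regime(-8, 8, h2 = h2))
  expect_equal(wide$mean_y, 0, tolerance = 1e-10)
  expect_equal(wide$var_y, 1, tolerance = 1e-6)
  expect_equal(wide$h2_s, h2, tolerance = 1e-6)
})

test_that("the genetic correlation is invariant under truncation selection", {
  r1 <- selection_regime(-1, 0.5, h2 = 0.3)
  r2 <- selection_regime(0, Inf, h2 = 0.3)
  out <- rg_under_selection(0.6, r1, r2)
  expect_equal(out$r_g, 0.6)
  expect_equal(rg_under_selection(0, r1, r2)$r_g, 0)
  expect_true(out$b1 > 0 && out$b2 > 0)
  expect_error(rg_under_selection(1.2, r1, r2), "correlation")
})
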