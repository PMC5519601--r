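#' Two-sided Wald test
#'
#' `p = 2 * (1 - Phi(|estimate - null| / se))`, assuming approximate
#' normality of the estimator.
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @param null_value Null value (default 0).
#' @return Two-sided p-value.
#' @examples
#' wald_test(0.597, 0.123, null_value = 1)
#' @export
wald_test <- function(estimate, se, null_value = 0) {
  if (!is.numeric(se) || any(se <= 0)) stop("'se' must be positive")
  2 * stats::pnorm(-abs(estimate - null_value) / se)
}

#' Genetic correlation between two blocks of a GREML fit
#'
#' `r_G = sigma_g_ij / sqrt(sigma_g_i^2 sigma_g_j^2)`, with its sampling
#' variance by the first-order delta method applied to the inverse
#' information matrix restricted to the three components involved, and
#' two-sided Wald tests against 0 (shared genetic effects) and against 1
#' (genotype-by-environment interaction when the blocks are environment
#' groups).  The estimate is unconstrained and may exceed 1 in magnitude.
#'
#' @param fit A converged `"greml"` fit.
#' @param i,j Block indices or group names.
#' @param grm Which genetic component to use in a multi-GRM fit
#'   (index or name, default the first).
#' @return An object of class `"genetic_correlation"`: a list with `pair`,
#'   `r_g`, `se`, `p_vs_0`, `p_vs_1`, and per-member `h2` with `se`
#'   (delta-method) from [h2_estimates()].
#' @examples
#' # see ?greml for a full simulated example
#' @export
genetic_correlation <- function(fit, i, j, grm = 1L) {
  stopifnot(inherits(fit, "greml"))
  if (!fit$converged) stop("fit has not converged")
  lev <- fit$groups
  if (is.character(i)) i <- match(i, lev)
  if (is.character(j)) j <- match(j, lev)
  if (is.character(grm)) grm <- match(grm, names(fit$sigma_g))
  if (anyNA(c(i, j, grm)) || i == j) stop("invalid block pair")
  pt <- fit$param_table
  ki <- which(pt$type == "g" & pt$grm == grm & pt$i == i & pt$j == i)
  kj <- which(pt$type == "g" & pt$grm == grm & pt$i == j & pt$j == j)
  kc <- which(pt$type == "g" & pt$grm == grm &
              pt$i == min(i, j) & pt$j == max(i, j))
  vi <- fit$theta[ki]; vj <- fit$theta[kj]; cv <- fit$theta[kc]
  if (fit$boundary[ki] || fit$boundary[kj]) {
    stop("genetic correlation undefined: a genetic variance is at its ",
         "floor for pair (", lev[i], ", ", lev[j], ")")
  }
  r_g <- cv / sqrt(vi * vj)
  se <- NA_real_
  if (fit$identifiable) {
    grad <- numeric(length(fit$theta))
    grad[ki] <- -cv / (2 * vi^1.5 * sqrt(vj))
    grad[kj] <- -cv / (2 * vj^1.5 * sqrt(vi))
    grad[kc] <- 1 / sqrt(vi * vj)
    v <- drop(t(grad) %*% fit$vcov %*% grad)
    if (is.finite(v) && v > 0) se <- sqrt(v)
  }
  h2 <- h2_estimates(fit)
  structure(list(
    pair = lev[c(i, j)], r_g = unname(r_g), se = unname(se),
    p_vs_0 = if (is.finite(se)) unname(wald_test(r_g, se, 0)) else NA_real_,
    p_vs_1 = if (is.finite(se)) unname(wald_test(r_g, se, 1)) else NA_real_,
    h2 = h2[h2$group %in% lev[c(i, j)], , drop = FALSE]
  ), class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, digits = 4, ...) {
  cat(sprintf("r_G(%s, %s) = %.*f (SE %.*f)\n", x$pair[1], x$pair[2],
              digits, x$r_g, digits, x$se))
  cat(sprintf("  p (vs 0) = %.3g, p (vs 1) = %.3g\n", x$p_vs_0, x$p_vs_1))
  invisible(x)
}

#' Share of genetic variance attributed to one genomic component
#'
#' For a multi-GRM fit partitioning the genetic variance over functional
#' SNP categories, the ratio of one component's genetic variance (`i = j`)
#' or covariance (`i != j`) to the total across components, with a
#' delta-method standard error and a one-sided test of enrichment beyond
#' the fraction of SNPs in the category (the expectation if the category's
#' SNPs behaved like a random draw).
#'
#' @param fit A converged multi-GRM `"greml"` fit.
#' @param component GRM index or name whose share is wanted.
#' @param i,j Block indices or names (default the first block's variance).
#' @param snp_fraction Fraction of SNPs in the component; when given, a
#'   one-sided enrichment p-value is reported.
#' @return A list with `ratio`, `se`, `snp_fraction`, `p_enrichment`.
#' @export
partition_ratio <- function(fit, component, i = 1L, j = i,
                            snp_fraction = NULL) {
  stopifnot(inherits(fit, "greml"))
  if (!fit$converged) stop("fit has not converged")
  lev <- fit$groups
  if (is.character(i)) i <- match(i, lev)
  if (is.character(j)) j <- match(j, lev)
  if (is.character(component)) component <- match(component,
                                                  names(fit$sigma_g))
  M <- length(fit$sigma_g)
  pt <- fit$param_table
  lo <- min(i, j); hi <- max(i, j)
  ks <- vapply(seq_len(M), function(m) {
    which(pt$type == "g" & pt$grm == m & pt$i == lo & pt$j == hi)
  }, 0L)
  x <- fit$theta[ks]
  S <- sum(x)
  if (abs(S) <= max(fit$floor)) {
    stop("total genetic variance is at the floor; ratio undefined")
  }
  ratio <- x[component] / S
  if (M == 1L) {
    return(list(ratio = 1, se = 0, snp_fraction = snp_fraction,
                p_enrichment = NA_real_))
  }
  se <- NA_real_
  if (fit$identifiable) {
    grad <- numeric(length(fit$theta))
    grad[ks] <- -x[component] / S^2
    grad[ks[component]] <- (S - x[component]) / S^2
    v <- drop(t(grad) %*% fit$vcov %*% grad)
    if (is.finite(v) && v > 0) se <- sqrt(v)
  }
  p_enr <- if (!is.null(snp_fraction) && is.finite(se) && se > 0) {
    stats::pnorm((ratio - snp_fraction) / se, lower.tail = FALSE)
  } else NA_real_
  list(ratio = unname(ratio), se = unname(se),
       snp_fraction = snp_fraction, p_enrichment = unname(p_enr))
}
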