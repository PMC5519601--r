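#' GBLUP prediction of genetic values in a target sample
#'
#' Best linear unbiased prediction of target-sample genetic values from
#' discovery-sample phenotypes under the single-GRM mixed model
#' `y = 1 mu + g + e`, `var(g) = A sigma_g^2`, with
#' `sigma_g^2 = h2 * var(y)` and `sigma_e^2 = (1 - h2) * var(y)`:
#' \deqn{\hat g_t = \sigma_g^2 A_{td} V_{dd}^{-1} (y_d - 1\hat\mu),}
#' the mean estimated by generalized least squares.  When the GRM is
#' `W W' / M` for a standardized dosage matrix `W`, this is identical to
#' ridge-regression BLUP on the SNPs with penalty
#' `lambda = M (1 - h2) / h2`.  Predictions are deterministic and linear
#' in the discovery phenotype, and shrink to zero as `h2 -> 0`.
#'
#' @param grm A `"grm"` covering discovery and target samples.
#' @param y_discovery Discovery phenotypes (covariate-adjusted), one per
#'   discovery sample.
#' @param discovery_ids,target_ids Disjoint sample ID vectors.
#' @param h2 Heritability used for shrinkage, in (0, 1).  The default
#'   (`NULL`) re-estimates it in the discovery set with a single-group
#'   [greml_fit()]; supplying a value overrides that.
#' @return Named numeric vector of predicted genetic values for
#'   `target_ids`, with the shrinkage heritability used in
#'   `attr(, "h2")`.
#' @examples
#' g <- simulate_genotypes(150, 100, seed = 1)
#' coh <- simulate_gxe_cohort(g, 150, matrix(0.4), 0.6,
#'                            covariates = NULL, seed = 2)
#' A <- compute_grm(g)
#' pred <- gblup_predict(A, coh$phenotype[1:100], coh$sample_id[1:100],
#'                       coh$sample_id[101:150], h2 = 0.4)
#' prediction_accuracy(pred, coh$phenotype[101:150])
#' @export
gblup_predict <- function(grm, y_discovery, discovery_ids, target_ids,
                          h2 = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (length(intersect(discovery_ids, target_ids))) {
    stop("discovery and target samples must be disjoint")
  }
  if (length(y_discovery) != length(discovery_ids)) {
    stop("'y_discovery' and 'discovery_ids' lengths differ")
  }
  if (is.null(h2)) {
    dfit <- greml_fit(y_discovery, rep("discovery", length(y_discovery)),
                      grm, ids = discovery_ids)
    h2 <- h2_estimates(dfit)$h2[1]
    h2 <- min(max(h2, 1e-4), 1 - 1e-4)
  }
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 >= 1) {
    stop("'h2' must be a single value in (0, 1)")
  }
  di <- match(discovery_ids, grm$samples)
  ti <- match(target_ids, grm$samples)
  if (anyNA(di) || anyNA(ti)) stop("sample IDs absent from the GRM")
  vp <- stats::var(y_discovery)
  sg <- h2 * vp; se <- (1 - h2) * vp
  V <- grm$values[di, di, drop = FALSE] * sg + diag(se, length(di))
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) {
    stop("singular mixed-model system (condition number ",
         format(kappa(V)), ")")
  })
  one <- rep(1, length(di))
  mu <- sum(Vi %*% y_discovery) / sum(Vi)
  out <- stats::setNames(
    drop(sg * grm$values[ti, di, drop = FALSE] %*% (Vi %*% (y_discovery - mu))),
    target_ids)
  attr(out, "h2") <- h2
  out
}

#' Genomic prediction accuracy
#'
#' Pearson correlation between predicted genetic values and observed
#' (adjusted) phenotypes in the target sample.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 3),
#'   neither constant.
#' @return The correlation.
#' @export
prediction_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3L) {
    stop("'predicted' and 'observed' must be equal-length vectors, n >= 3")
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("prediction accuracy undefined for constant input")
  }
  stats::cor(predicted, observed)
}

#' Single-SNP association scan
#'
#' Per-variant simple linear regression of an adjusted phenotype on the
#' allele dosage within a sample subset: slope, standard error,
#' t-statistic and two-sided p-value, with variants monomorphic in the
#' subset flagged and not tested.  Covariate adjustment is expected
#' upstream ([adjust_phenotype()]); genome-wide significance is annotated
#' at `5e-8`.
#'
#' @param G A `"genotype_matrix"`.
#' @param y Adjusted phenotype, one value per selected sample.
#' @param samples Optional sample IDs (or indices) selecting the analysis
#'   subset of `G`; default all samples.
#' @return A `data.frame` with one row per variant: `snp`, `chr`, `pos`,
#'   `n`, `beta`, `se`, `t`, `p`, `genome_wide`, `tested`.
#' @examples
#' g <- simulate_genotypes(200, 50, seed = 1)
#' res <- gwas_scan(g, rnorm(200))
#' genomic_lambda(res)
#' @export
gwas_scan <- function(G, y, samples = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosage
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, rownames(dos))
           else samples
    if (anyNA(idx)) stop("unknown sample IDs in 'samples'")
    dos <- dos[idx, , drop = FALSE]
  }
  n <- nrow(dos)
  if (length(y) != n) stop("'y' must have one value per selected sample")
  if (n <= 2L) stop("need more than 2 samples for association testing")
  if (stats::sd(y, na.rm = TRUE) == 0) {
    stop("constant phenotype: association tests undefined")
  }
  mask <- (!is.na(dos)) * 1
  Xz <- dos; Xz[is.na(Xz)] <- 0
  nm <- colSums(mask)
  sx <- colSums(Xz)
  sxx <- colSums(Xz^2)
  sy <- drop(crossprod(mask, y))
  syy <- drop(crossprod(mask, y^2))
  sxy <- drop(crossprod(Xz, y))
  Sxx <- sxx - sx^2 / nm
  Sxy <- sxy - sx * sy / nm
  Syy <- syy - sy^2 / nm
  tested <- nm > 2 & Sxx > 1e-12
  beta <- se <- tval <- pval <- rep(NA_real_, ncol(dos))
  b <- Sxy[tested] / Sxx[tested]
  rss <- pmax(Syy[tested] - b * Sxy[tested], 0)
  df <- nm[tested] - 2
  s <- sqrt(rss / df / Sxx[tested])
  tv <- b / s
  beta[tested] <- b
  se[tested] <- s
  tval[tested] <- tv
  pval[tested] <- 2 * stats::pt(-abs(tv), df)
  data.frame(snp = G$map$id, chr = G$map$chr, pos = G$map$pos,
             n = as.integer(nm), beta = beta, se = se, t = tval, p = pval,
             genome_wide = !is.na(pval) & pval < 5e-8, tested = tested)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi^2) / qchisq(0.5, 1)` over the tested variants of a
#' [gwas_scan()] result (the squared t-statistics serve as the chi-square
#' statistics); values near 1 indicate a well-calibrated null.
#'
#' @param gwas A `data.frame` from [gwas_scan()].
#' @return The inflation factor.
#' @export
genomic_lambda <- function(gwas) {
  stopifnot(is.data.frame(gwas), "t" %in% names(gwas))
  chisq <- gwas$t[gwas$tested]^2
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, 1)
}
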