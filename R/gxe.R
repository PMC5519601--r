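#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 24)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)")
  }
  if (!is.numeric(n_tests) || n_tests < 1) {
    stop("'n_tests' must be a positive count")
  }
  alpha / n_tests
}

#' Genome-wide G-by-E scan across environment groups
#'
#' One joint K-variate GREML fit over the environment groups of a cohort,
#' followed by all `K(K-1)/2` pairwise genetic correlations with Wald tests
#' against 1 (the no-interaction null) and per-group SNP-heritabilities
#' with tests against 0.  The reported multiple-testing threshold is
#' `alpha / (n_traits * K(K-1)/2)`, Bonferroni over every contrast of the
#' study (e.g. 4 traits x 6 contrasts gives 0.05 / 24).
#'
#' Groups smaller than `min_group` are dropped with a warning (reducing K)
#' rather than destabilizing the joint fit.
#'
#' @param cohort Cohort `data.frame` with `sample_id`, `group` and
#'   `phenotype` columns (see [stratify()]; the phenotype is expected to be
#'   covariate-adjusted upstream, see [adjust_phenotype()]).
#' @param grm A `"grm"` covering the cohort samples.
#' @param alpha Family-wise error level (default 0.05).
#' @param n_traits Number of traits in the full study design contributing
#'   to the multiple-testing burden (default 1).
#' @param min_group Minimum group size (default 50).
#' @param ... Passed to [greml_fit()].
#' @return An object of class `"gxe_scan"`: a list with `fit` (the
#'   `"greml"` object), `h2` (per-group table), `r_g` (pairwise contrast
#'   table with `estimate`, `se`, `p_vs_1`, `p_vs_0`), `n_tests`,
#'   `threshold`, `alpha`, `dropped_groups`.
#' @examples
#' # see the package vignette for an end-to-end simulated scan
#' @export
gxe_scan <- function(cohort, grm, alpha = 0.05, n_traits = 1L,
                     min_group = 50L, ...) {
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "group", "phenotype") %in% names(cohort)))
  grp <- droplevels(as.factor(cohort$group))
  sizes <- table(grp)
  small <- names(sizes)[sizes < min_group]
  if (length(small)) {
    warning("dropping group(s) below the size floor (", min_group, "): ",
            paste(small, collapse = ", "))
    keep <- !(grp %in% small)
    cohort <- cohort[keep, , drop = FALSE]
    grp <- droplevels(grp[keep])
  }
  K <- nlevels(grp)
  if (K < 2L) stop("need at least two groups for a G x E scan")
  fit <- greml_fit(cohort$phenotype, grp, grm, ids = cohort$sample_id,
                   mode = "gxe", ...)
  n_pairs <- K * (K - 1L) / 2L
  n_tests <- n_traits * n_pairs
  pairs <- which(upper.tri(diag(K)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  rg <- do.call(rbind, lapply(seq_len(n_pairs), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    gc <- tryCatch(genetic_correlation(fit, i, j), error = function(e) e)
    if (inherits(gc, "error")) {
      data.frame(group_i = fit$groups[i], group_j = fit$groups[j],
                 estimate = NA_real_, se = NA_real_,
                 p_vs_1 = NA_real_, p_vs_0 = NA_real_,
                 note = conditionMessage(gc))
    } else {
      data.frame(group_i = fit$groups[i], group_j = fit$groups[j],
                 estimate = gc$r_g, se = gc$se,
                 p_vs_1 = gc$p_vs_1, p_vs_0 = gc$p_vs_0, note = "")
    }
  }))
  structure(list(fit = fit, h2 = h2_estimates(fit), r_g = rg,
                 n_tests = n_tests,
                 threshold = bonferroni_threshold(alpha, n_tests),
                 alpha = alpha, dropped_groups = small),
            class = "gxe_scan")
}

#' @export
print.gxe_scan <- function(x, digits = 3, ...) {
  cat("G x E scan over", length(x$fit$groups), "environment groups (N =",
      x$fit$N, ")\n")
  cat("SNP-heritability (test vs 0):\n")
  print(format(x$h2, digits = digits), quote = FALSE)
  cat("Genetic correlations (test vs 1 = no G x E):\n")
  print(format(x$r_g[setdiff(names(x$r_g), "note")], digits = digits),
        quote = FALSE)
  cat(sprintf("Bonferroni threshold: %.4g (alpha %.3g over %d tests)\n",
              x$threshold, x$alpha, x$n_tests))
  invisible(x)
}

#' Write a G-by-E scan as a results TSV
#'
#' One row per estimate, mirroring the published table layout: per-group
#' heritabilities (test type `a`, against 0) followed by pairwise genetic
#' correlations (test type `b`, against 1).
#'
#' @param scan A `"gxe_scan"`.
#' @param path File path.
#' @export
write_gxe_scan <- function(scan, path) {
  h <- data.frame(term = paste0("h2(", scan$h2$group, ")"),
                  estimate = scan$h2$h2, se = scan$h2$se, p = scan$h2$p,
                  test = "a")
  r <- data.frame(term = paste0("r_G(", scan$r_g$group_i, ",",
                                scan$r_g$group_j, ")"),
                  estimate = scan$r_g$estimate, se = scan$r_g$se,
                  p = scan$r_g$p_vs_1, test = "b")
  utils::write.table(rbind(h, r), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Permutation test for a pairwise G-by-E contrast
#'
#' Empirical null distribution of the genetic correlation between two
#' environment groups under random reassignment of the environmental
#' status.  Labels are shuffled jointly across the union of the two groups
#' with the original group sizes preserved; each permuted dataset is
#' refitted by bivariate GREML and the deviation `|r_G - 1|` from the
#' no-interaction null is recorded.  The empirical p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (n_perm + 1)`, so the
#' smallest attainable p with 1000 permutations is 1/1001.  Non-convergent
#' permutation fits are redrawn up to `retry` times each; if more than 20%
#' of permutations ultimately fail the test aborts.
#'
#' @param cohort Cohort `data.frame` (`sample_id`, `group`, `phenotype`).
#' @param grm A `"grm"`.
#' @param pair Length-2 character vector naming the contrasted groups.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @param retry Redraw attempts per non-convergent permutation (default 3).
#' @param ... Passed to [greml_fit()].
#' @return A list with `p` (empirical p-value), `observed` (the observed
#'   `"genetic_correlation"`), `null_rg` (vector of permuted estimates),
#'   `n_failed`.
#' @export
permutation_test <- function(cohort, grm, pair, n_perm = 1000L, seed = NULL,
                             retry = 3L, ...) {
  stopifnot(length(pair) == 2L)
  sub <- cohort[cohort$group %in% pair, , drop = FALSE]
  grp <- factor(as.character(sub$group), levels = pair)
  if (!is.null(seed)) set.seed(seed)
  fit <- greml_fit(sub$phenotype, grp, grm, ids = sub$sample_id,
                   mode = "gxe", ...)
  obs <- genetic_correlation(fit, 1L, 2L)
  obs_dev <- abs(obs$r_g - 1)
  n1 <- sum(grp == pair[1])
  n <- length(grp)
  null_rg <- rep(NA_real_, n_perm)
  n_failed <- 0L
  for (b in seq_len(n_perm)) {
    for (a in seq_len(retry + 1L)) {
      lab <- rep(pair[2], n)
      lab[sample.int(n, n1)] <- pair[1]
      pfit <- tryCatch({
        f <- greml_fit(sub$phenotype, factor(lab, levels = pair), grm,
                       ids = sub$sample_id, mode = "gxe", ...)
        genetic_correlation(f, 1L, 2L)$r_g
      }, error = function(e) NULL)
      if (!is.null(pfit)) { null_rg[b] <- pfit; break }
    }
    if (is.na(null_rg[b])) n_failed <- n_failed + 1L
  }
  if (n_failed > 0.2 * n_perm) {
    stop("more than 20% of permutation fits failed to converge (",
         n_failed, "/", n_perm, ")")
  }
  ok <- !is.na(null_rg)
  p <- (1 + sum(abs(null_rg[ok] - 1) >= obs_dev)) / (sum(ok) + 1)
  list(p = p, observed = obs, null_rg = null_rg, n_failed = n_failed)
}

#' Sex-stratified G-by-E scan
#'
#' Splits each environment group by sex (an eight-variate fit for the
#' four-way exposure cross) and runs the same joint scan as [gxe_scan()].
#' Contrasts between males and females within the same environment are
#' flagged in a `sex_contrast` column: a genetic correlation below 1 there
#' indicates genotype-by-sex interaction rather than G x E proper.  Groups
#' missing one sex (or otherwise below the size floor) are dropped with a
#' warning, reducing K.
#'
#' @param cohort Cohort `data.frame` with `sample_id`, `group`, `sex`
#'   (`M`/`F`) and `phenotype`.
#' @inheritParams gxe_scan
#' @return A `"gxe_scan"` whose `r_g` table carries a logical
#'   `sex_contrast` column.
#' @export
sex_stratified_scan <- function(cohort, grm, alpha = 0.05, n_traits = 1L,
                                min_group = 50L, ...) {
  stopifnot("sex" %in% names(cohort))
  sex <- toupper(as.character(cohort$sex))
  ok <- sex %in% c("M", "F") & !is.na(cohort$group)
  cohort <- cohort[ok, , drop = FALSE]
  cohort$group <- paste0(as.character(cohort$group), "_", sex[ok])
  scan <- gxe_scan(cohort, grm, alpha = alpha, n_traits = n_traits,
                   min_group = min_group, ...)
  env_of <- function(g) sub("_[MF]$", "", g)
  scan$r_g$sex_contrast <- env_of(scan$r_g$group_i) ==
    env_of(scan$r_g$group_j)
  scan
}
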