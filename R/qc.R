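#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed
#' genotype counts against Hardy-Weinberg proportions computed from the
#' sample allele frequency (no continuity correction).  Monomorphic counts
#' carry no testable disequilibrium and return p = 1.  Vectorized over
#' count triples.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (equal-length
#'   vectors allowed).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @examples
#' hwe_test(25, 50, 25)   # exactly at HW proportions: p = 1
#' hwe_test(50, 0, 50)    # maximal disequilibrium
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0, na.rm = TRUE)) {
    stop("genotype counts must be non-negative")
  }
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0, na.rm = TRUE)) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  e_AA <- n * p^2
  e_Aa <- n * 2 * p * (1 - p)
  e_aa <- n * (1 - p)^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  stat <- term(n_AA, e_AA) + term(n_Aa, e_Aa) + term(n_aa, e_aa)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Variant- and sample-level genotype quality control
#'
#' Applies the standard GWAS filters in a fixed order: variants failing the
#' minor-allele-frequency, Hardy-Weinberg or missingness thresholds are
#' removed first (counted against the first failed filter, in that
#' precedence order), then samples failing the missingness threshold on the
#' surviving variants are removed.  Defaults are MAF > 0.01, HWE p >= 1e-4,
#' variant missingness <= 0.05, sample missingness <= 0.05.
#'
#' @param G A `"genotype_matrix"`.
#' @param maf_min Minimum minor allele frequency (exclusive), in `[0, 0.5)`.
#' @param hwe_p_min Minimum HWE p-value (inclusive), in `[0, 1]`.
#' @param var_miss_max Maximum variant missingness (inclusive).
#' @param sample_miss_max Maximum sample missingness (inclusive).
#' @return A list with `genotypes` (the filtered `"genotype_matrix"`) and
#'   `report`, a `"qc_report"` with per-filter removal counts and the
#'   thresholds used.  If every variant is removed the report carries
#'   `empty = TRUE` and a warning is raised (no error).
#' @examples
#' g <- simulate_genotypes(100, 50, seed = 1)
#' qc <- qc_filter(g)
#' qc$report
#' @export
qc_filter <- function(G, maf_min = 0.01, hwe_p_min = 1e-4,
                      var_miss_max = 0.05, sample_miss_max = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (maf_min < 0 || maf_min >= 0.5) stop("'maf_min' must be in [0, 0.5)")
  if (hwe_p_min < 0 || hwe_p_min > 1) stop("'hwe_p_min' must be in [0, 1]")
  if (var_miss_max < 0 || var_miss_max > 1 ||
      sample_miss_max < 0 || sample_miss_max > 1) {
    stop("missingness thresholds must be in [0, 1]")
  }
  dos <- G$dosage
  freq <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  n_AA <- colSums(dos == 2L, na.rm = TRUE)
  n_Aa <- colSums(dos == 1L, na.rm = TRUE)
  n_aa <- colSums(dos == 0L, na.rm = TRUE)
  hwe_p <- rep(1, ncol(dos))
  nonzero <- (n_AA + n_Aa + n_aa) > 0
  hwe_p[nonzero] <- hwe_test(n_AA[nonzero], n_Aa[nonzero], n_aa[nonzero])
  vmiss <- colMeans(is.na(dos))

  fail_maf <- !is.finite(maf) | maf <= maf_min
  fail_hwe <- !fail_maf & hwe_p < hwe_p_min
  fail_vmiss <- !fail_maf & !fail_hwe & vmiss > var_miss_max
  keep_var <- !(fail_maf | fail_hwe | fail_vmiss)

  dos2 <- dos[, keep_var, drop = FALSE]
  smiss <- if (ncol(dos2)) rowMeans(is.na(dos2)) else rep(0, nrow(dos2))
  keep_sample <- smiss <= sample_miss_max

  out <- structure(list(
    dosage = dos2[keep_sample, , drop = FALSE],
    map = G$map[keep_var, , drop = FALSE],
    freqs = NULL), class = "genotype_matrix")
  out$freqs <- colMeans(out$dosage, na.rm = TRUE) / 2

  report <- structure(list(
    thresholds = c(maf_min = maf_min, hwe_p_min = hwe_p_min,
                   var_miss_max = var_miss_max,
                   sample_miss_max = sample_miss_max),
    variants_in = ncol(dos), variants_out = ncol(dos2),
    samples_in = nrow(dos), samples_out = sum(keep_sample),
    removed = c(maf = sum(fail_maf), hwe = sum(fail_hwe),
                var_missingness = sum(fail_vmiss),
                sample_missingness = sum(!keep_sample)),
    empty = ncol(dos2) == 0L
  ), class = "qc_report")
  if (report$empty) warning("all variants removed by QC")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC:", x$variants_in, "->", x$variants_out, "variants;",
      x$samples_in, "->", x$samples_out, "samples\n")
  cat("  removed per filter:",
      paste(names(x$removed), x$removed, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report A `"qc_report"`.
#' @param path File path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(filter = names(report$removed),
                   removed = as.integer(report$removed))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy pruning of related individuals
#'
#' Repeatedly removes the individual involved in the largest number of
#' pairs with relationship above `threshold` until no such pair remains.
#' Ties in degree are broken deterministically by removing the individual
#' whose sample ID sorts last.
#'
#' @param grm A `"grm"` object.
#' @param threshold Relationship cutoff (> 0); the conventional value for
#'   excluding cryptic relatedness in population samples is 0.05.
#' @return Character vector of retained sample IDs, in the input order.
#' @examples
#' g <- simulate_genotypes(20, 100, seed = 1)
#' A <- compute_grm(g)
#' length(prune_related(A, threshold = 0.05))
#' @export
prune_related <- function(grm, threshold = 0.05) {
  stopifnot(inherits(grm, "grm"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("'threshold' must be positive")
  }
  A <- grm$values > threshold
  diag(A) <- FALSE
  active <- rep(TRUE, nrow(A))
  ids <- grm$samples
  repeat {
    deg <- rowSums(A[, active, drop = FALSE]) * active
    mx <- max(deg)
    if (mx == 0) break
    cand <- which(deg == mx)
    drop <- cand[order(ids[cand])][length(cand)]
    active[drop] <- FALSE
  }
  ids[active]
}
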