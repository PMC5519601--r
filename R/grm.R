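#' Genomic relationship matrix
#'
#' The allele-frequency-standardized estimator
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_m
#'   \frac{(x_{jm} - 2p_m)(x_{km} - 2p_m)}{2 p_m (1 - p_m)}}
#' with allele frequencies estimated from the sample, monomorphic variants
#' skipped, and the per-pair divisor \eqn{M_{jk}} the number of variants
#' non-missing in both individuals (missing dosages contribute zero to the
#' numerator, i.e. are mean-imputed to \eqn{2p} on the standardized scale).
#' On complete data this reduces to \eqn{W W' / M} with \eqn{W} the
#' column-standardized dosage matrix.
#'
#' @param G A `"genotype_matrix"` with at least one polymorphic variant.
#' @return An object of class `"grm"`: a list with `values` (symmetric
#'   n x n matrix with sample dimnames), `samples`, and `n_snps` (n x n
#'   matrix of per-pair variant counts).
#' @examples
#' g <- simulate_genotypes(10, 200, seed = 1)
#' A <- compute_grm(g)
#' mean(diag(A$values))  # near 1 under Hardy-Weinberg equilibrium
#' @export
compute_grm <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosage
  p <- colMeans(dos, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic variants available for the GRM")
  dos <- dos[, poly, drop = FALSE]
  std <- .standardize_dosage(dos, p[poly])
  w <- std$w
  obs <- (!is.na(dos)) * 1
  npair <- tcrossprod(obs)
  if (any(npair == 0)) {
    stop("some sample pair shares no non-missing variant; ",
         "cannot resolve the full relationship matrix")
  }
  A <- tcrossprod(w) / npair
  dimnames(A) <- list(rownames(dos), rownames(dos))
  structure(list(values = A, samples = rownames(dos), n_snps = npair),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- length(x$samples)
  cat("grm:", n, "samples; mean diagonal",
      format(mean(diag(x$values)), digits = 4), "; variants per pair",
      format(mean(x$n_snps), digits = 4), "\n")
  invisible(x)
}

#' Subset a GRM to a set of samples
#'
#' @param x A `"grm"`.
#' @param i Sample IDs or indices.
#' @param ... Ignored.
#' @return The sub-GRM over the requested samples.
#' @export
`[.grm` <- function(x, i, ...) {
  idx <- if (is.character(i)) match(i, x$samples) else i
  if (anyNA(idx)) stop("unknown sample IDs in GRM subset")
  structure(list(values = x$values[idx, idx, drop = FALSE],
                 samples = x$samples[idx],
                 n_snps = if (is.matrix(x$n_snps))
                   x$n_snps[idx, idx, drop = FALSE] else x$n_snps),
            class = "grm")
}

#' Coerce a relationship matrix to a `"grm"` object
#'
#' @param values Symmetric numeric matrix; sample IDs from dimnames unless
#'   given.
#' @param samples Optional sample IDs.
#' @param n_snps Per-pair variant count (scalar or matrix); informational.
#' @return A `"grm"`.
#' @export
as_grm <- function(values, samples = NULL, n_snps = NA_real_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) ||
      max(abs(values - t(values))) > 1e-8) {
    stop("'values' must be a symmetric matrix")
  }
  if (is.null(samples)) samples <- rownames(values)
  if (is.null(samples)) samples <- sprintf("id%d", seq_len(nrow(values)))
  dimnames(values) <- list(samples, samples)
  structure(list(values = values, samples = samples, n_snps = n_snps),
            class = "grm")
}
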