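#' Simulate biallelic SNP genotypes in linkage equilibrium
#'
#' Draws per-variant allele frequencies uniformly from `maf_range` and
#' per-individual dosages as Binomial(2, p) under Hardy-Weinberg
#' equilibrium.  Variants are assigned synthetic chromosome/position
#' coordinates.  Linkage disequilibrium is deliberately absent: the
#' variance-component identities exercised downstream do not depend on it.
#'
#' @param n_samples Number of individuals (>= 1).
#' @param n_snps Number of variants (>= 1).
#' @param maf_range Length-2 numeric, lower/upper bound of the allele
#'   frequency draw, each in (0, 0.5].
#' @param missing_rate Proportion of dosages set missing at random,
#'   in `[0, 1)`.
#' @param seed Optional integer seed; identical inputs give bit-identical
#'   output.
#' @return An object of class `"genotype_matrix"`: a list with
#'   \describe{
#'     \item{dosage}{n x M integer matrix of 0/1/2 counts of the A1 allele,
#'       `NA` where missing, with sample/variant dimnames.}
#'     \item{map}{data.frame of variant chromosome, id, position, alleles.}
#'     \item{freqs}{per-variant A1 allele frequency (the generative draw
#'       here; the sample estimate when read from disk).}
#'   }
#' @examples
#' g <- simulate_genotypes(50, 20, seed = 1)
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = NULL) {
  if (!is.numeric(n_samples) || n_samples < 1 ||
      !is.numeric(n_snps) || n_snps < 1) {
    stop("'n_samples' and 'n_snps' must be positive")
  }
  n <- as.integer(n_samples); m <- as.integer(n_snps)
  if (length(maf_range) != 2L || maf_range[1] <= 0 ||
      maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("'maf_range' must satisfy 0 < low <= high <= 0.5")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("'missing_rate' must be in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(m, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  if (missing_rate > 0) {
    dos[stats::runif(n * m) < missing_rate] <- NA_integer_
  }
  samples <- sprintf("id%0*d", nchar(n), seq_len(n))
  map <- data.frame(
    chr = rep(seq_len(min(22L, m)), length.out = m),
    id = sprintf("snp%d", seq_len(m)),
    pos = 1000L * seq_len(m),
    a1 = "A", a2 = "G",
    stringsAsFactors = FALSE
  )
  dimnames(dos) <- list(samples, map$id)
  structure(list(dosage = dos, map = map, freqs = stats::setNames(p, map$id)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants;", sum(is.na(x$dosage)), "missing dosages\n")
  invisible(x)
}

#' Sample allele frequencies of a genotype matrix
#'
#' Per-variant A1 allele frequency estimated from the observed (non-missing)
#' dosages.
#'
#' @param G A `"genotype_matrix"`.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_freq <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  colMeans(G$dosage, na.rm = TRUE) / 2
}

# Column-standardized dosages w = (x - 2p) / sqrt(2p(1-p)), with missing
# entries set to 0 (i.e. mean-imputed on the standardized scale).
.standardize_dosage <- function(dos, p = NULL) {
  if (is.null(p)) p <- colMeans(dos, na.rm = TRUE) / 2
  denom <- sqrt(2 * p * (1 - p))
  w <- sweep(dos, 2L, 2 * p, `-`)
  w <- sweep(w, 2L, denom, `/`)
  w[is.na(w) | is.nan(w) | is.infinite(w)] <- 0
  list(w = w, p = p, poly = denom > 0)
}

#' Simulate an environment-stratified cohort with known G-by-E architecture
#'
#' Builds phenotypes `y = covariate effects + g + e` for `K` disjoint
#' environment groups drawn from a common genotype pool.  The genetic
#' architecture is infinitesimal: every SNP is causal, with per-group
#' Gaussian effect vectors whose across-group covariance (on the
#' standardized-genotype scale) is controlled so that the genetic values
#' satisfy `cov(g_i, g_j) = sigma_g[i, j]`.  Cross-group correlation is
#' induced at the SNP-effect level (Cholesky factor of the effect
#' correlation matrix applied to independent Gaussian vectors), matching a
#' design in which no individual is observed in more than one environment
#' and there is therefore no residual covariance between groups.
#'
#' @param G A `"genotype_matrix"` providing the genotype pool.
#' @param n_per_group Integer vector of group sizes; `sum(n_per_group)` must
#'   not exceed the pool size.  Groups are filled with consecutive samples.
#' @param sigma_g K x K symmetric positive semidefinite true genetic
#'   covariance matrix (per-group genetic variances on the diagonal).
#' @param sigma_e Length-K positive residual variances.
#' @param covariates List describing fixed-effect confounders, each element
#'   `list(name =, kind = "continuous"|"binary"|"factor", effect =)`.
#'   Continuous covariates are N(0,1), binary are Bernoulli(1/2) coded 0/1,
#'   and factors have three equiprobable levels one-hot coded against the
#'   first; `effect` multiplies the coded column(s).  The default emulates
#'   sex, a year-of-birth-like continuous confounder and a measurement
#'   batch.  Use `covariates = NULL` for none.
#' @param group_names Optional group labels; defaults to the
#'   breastfeeding-by-maternal-smoking cross `B&NS, B&S, NB&NS, NB&S` when
#'   `K = 4`, else `G1..GK`.
#' @param nonnormal If `TRUE`, a monotone skewing transform
#'   (`exp(y / 2)`) is applied to the returned phenotype, to exercise
#'   rank-based normalization downstream.
#' @param seed Optional integer seed.
#' @return A `data.frame` (the cohort table) with columns `sample_id`,
#'   `group`, covariate columns, `g_true` (the simulated genetic value,
#'   kept for validation) and `phenotype`.  When the group labels are the
#'   four-way cross, `breastfed` and `maternal_smoking` label columns are
#'   attached.  The matrix of standardized SNP effects is stored in
#'   `attr(, "effects")`.
#' @examples
#' g <- simulate_genotypes(300, 200, seed = 1)
#' sg <- matrix(c(0.2, 0.12, 0.12, 0.2), 2)
#' coh <- simulate_gxe_cohort(g, c(150, 150), sg, c(0.8, 0.8), seed = 2)
#' table(coh$group)
#' @export
simulate_gxe_cohort <- function(G, n_per_group, sigma_g, sigma_e,
                                covariates = default_covariates(),
                                group_names = NULL, nonnormal = FALSE,
                                seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  K <- length(n_per_group)
  sigma_g <- as.matrix(sigma_g)
  if (nrow(sigma_g) != K || ncol(sigma_g) != K ||
      max(abs(sigma_g - t(sigma_g))) > 1e-8) {
    stop("'sigma_g' must be a symmetric ", K, "x", K, " matrix")
  }
  ev <- eigen(sigma_g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("'sigma_g' is not positive semidefinite")
  }
  if (length(sigma_e) != K || any(sigma_e <= 0)) {
    stop("'sigma_e' must hold ", K, " positive residual variances")
  }
  n_tot <- sum(n_per_group)
  if (n_tot > nrow(G$dosage)) {
    stop("group sizes (", n_tot, ") exceed the genotype pool (",
         nrow(G$dosage), ")")
  }
  if (is.null(group_names)) {
    group_names <- if (K == 4) c("B&NS", "B&S", "NB&NS", "NB&S")
                   else paste0("G", seq_len(K))
  }
  if (!is.null(seed)) set.seed(seed)

  idx <- seq_len(n_tot)
  dos <- G$dosage[idx, , drop = FALSE]
  std <- .standardize_dosage(dos)
  w <- std$w[, std$poly, drop = FALSE]
  m <- ncol(w)
  grp <- factor(rep(group_names, times = n_per_group), levels = group_names)

  # correlated per-SNP effects: columns of B have correlation cor(sigma_g)
  sdg <- sqrt(diag(sigma_g))
  R <- diag(K)
  pos <- sdg > 0
  if (any(pos)) {
    R[pos, pos] <- sigma_g[pos, pos, drop = FALSE] /
      tcrossprod(sdg[pos])
  }
  L <- .psd_chol(R)
  B <- matrix(stats::rnorm(m * K), m, K) %*% t(L)
  B <- sweep(B, 2L, sdg / sqrt(m), `*`)

  g_true <- numeric(n_tot)
  e <- numeric(n_tot)
  for (k in seq_len(K)) {
    rows <- which(as.integer(grp) == k)
    g_true[rows] <- w[rows, , drop = FALSE] %*% B[, k]
    e[rows] <- stats::rnorm(length(rows), sd = sqrt(sigma_e[k]))
  }

  cov_df <- .draw_covariates(covariates, n_tot)
  y <- cov_df$contribution + g_true + e
  if (nonnormal) y <- exp(y / 2)

  out <- data.frame(sample_id = rownames(dos), group = grp,
                    stringsAsFactors = FALSE)
  if (ncol(cov_df$table)) out <- cbind(out, cov_df$table)
  if (identical(group_names, c("B&NS", "B&S", "NB&NS", "NB&S"))) {
    out$breastfed <- ifelse(grp %in% c("B&NS", "B&S"), "yes", "no")
    out$maternal_smoking <- ifelse(grp %in% c("B&S", "NB&S"), "yes", "no")
  }
  out$g_true <- g_true
  out$phenotype <- y
  attr(out, "effects") <- B
  out
}

# lower-triangular factor L with L %*% t(L) = R, tolerant of PSD rank loss
.psd_chol <- function(R) {
  ed <- eigen(R, symmetric = TRUE)
  val <- pmax(ed$values, 0)
  ed$vectors %*% diag(sqrt(val), nrow = length(val))
}

#' Default covariate specification for the cohort simulator
#'
#' Sex (binary, effect 0.1 phenotypic SD), a year-of-birth-like continuous
#' confounder (effect 0.1) and a three-level measurement-batch factor
#' (effect 0.05 per coded level).
#'
#' @return A list of covariate descriptors for [simulate_gxe_cohort()].
#' @export
default_covariates <- function() {
  list(list(name = "sex", kind = "binary", effect = 0.1),
       list(name = "yob", kind = "continuous", effect = 0.1),
       list(name = "batch", kind = "factor", effect = 0.05))
}

.draw_covariates <- function(spec, n) {
  tab <- data.frame(row.names = seq_len(n))
  contribution <- numeric(n)
  for (cv in spec) {
    kind <- match.arg(cv$kind, c("continuous", "binary", "factor"))
    if (kind == "continuous") {
      x <- stats::rnorm(n)
      contribution <- contribution + cv$effect * x
    } else if (kind == "binary") {
      x <- stats::rbinom(n, 1L, 0.5)
      contribution <- contribution + cv$effect * x
      if (identical(cv$name, "sex")) x <- c("M", "F")[x + 1L]
    } else {
      lev <- paste0("b", 1:3)
      x <- factor(sample(lev, n, replace = TRUE), levels = lev)
      contribution <- contribution + cv$effect * (as.integer(x) - 1L)
    }
    tab[[cv$name]] <- x
  }
  list(table = tab, contribution = contribution)
}

#' Apply truncation selection to a cohort
#'
#' Retains the rows of `cohort` whose selection variable falls in the
#' truncation interval `(t1, t2)` of the regime.  The selection variable is
#' the standardized phenotype itself when `r = 1`, or a unit-variance
#' variable with correlation `r` to it otherwise (built as
#' `r * y + sqrt(1 - r^2) * z`, `z` independent standard normal -- an
#' environmental variable with no genetic component of its own beyond what
#' it borrows from `y`).  The phenotype is standardized internally before
#' selection, matching the standard-normal scale of the thresholds.
#'
#' @param cohort A cohort `data.frame` with a `phenotype` column.
#' @param regime A [selection_regime()].
#' @param seed Optional seed for the correlated selection variable.
#' @return The selected subset of `cohort`, with the realized selection
#'   proportion in `attr(, "realized_proportion")`.
#' @examples
#' g <- simulate_genotypes(200, 50, seed = 1)
#' coh <- simulate_gxe_cohort(g, 200, matrix(0.2), 0.8, seed = 2)
#' sel <- apply_selection(coh, selection_regime(-1, 1, h2 = 0.2), seed = 3)
#' attr(sel, "realized_proportion")
#' @export
apply_selection <- function(cohort, regime, seed = NULL) {
  stopifnot(is.data.frame(cohort), "phenotype" %in% names(cohort),
            inherits(regime, "selection_regime"))
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(scale(cohort$phenotype))
  s <- if (regime$r == 1) y else {
    regime$r * y + sqrt(1 - regime$r^2) * stats::rnorm(length(y))
  }
  keep <- s > regime$t1 & s < regime$t2
  prop <- mean(keep)
  if (!any(keep)) {
    stop("selection retained no individuals (realized proportion ",
         format(prop), ")")
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "realized_proportion") <- prop
  out
}

#' Read or write a cohort table as TSV
#'
#' Plain tab-separated cohort table with a `sample_id` column, matching the
#' output of [simulate_gxe_cohort()].
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort()` returns the cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
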