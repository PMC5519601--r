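# Independent oracles used across tests.  These deliberately avoid the
# package's internal code paths: V is assembled by explicit loops, the
# restricted likelihood uses determinant()/solve() rather than Cholesky
# updates, and optimization is a generic direct search.

# restricted log-likelihood of the multivariate GREML model, evaluated
# directly from its definition
oracle_reml_logL <- function(theta, y, blk, A, sigma_e_offdiag = NULL) {
  # theta: for K groups with one GRM, c(vg_11, vg_12, ..., vg_KK upper
  # triangle by column, ve_1..ve_K)
  K <- length(unique(blk))
  N <- length(y)
  ut <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 2L], ut[, 1L]), , drop = FALSE]  # column-major upper
  Sg <- matrix(0, K, K)
  for (r in seq_len(nrow(ut))) {
    Sg[ut[r, 1L], ut[r, 2L]] <- Sg[ut[r, 2L], ut[r, 1L]] <- theta[r]
  }
  ve <- theta[nrow(ut) + seq_len(K)]
  V <- matrix(0, N, N)
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      V[a, b] <- A[a, b] * Sg[blk[a], blk[b]]
      if (a == b) V[a, b] <- V[a, b] + ve[blk[a]]
    }
  }
  X <- matrix(0, N, K)
  X[cbind(seq_len(N), blk)] <- 1
  ld <- determinant(V, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  ldx <- determinant(XtViX, logarithm = TRUE)
  if (ldx$sign <= 0) return(-Inf)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (ld$modulus + ldx$modulus + t(y) %*% P %*% y +
                     (N - ncol(X)) * log(2 * pi)))
}

# direct maximization of the restricted likelihood by Nelder-Mead from
# several starts (log-parameterized variances to stay in bounds)
oracle_reml_fit <- function(y, blk, A) {
  K <- length(unique(blk))
  nut <- K * (K + 1) / 2
  obj <- function(par) {
    # variances on log scale, covariances free
    theta <- numeric(nut + K)
    ut <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
    ut <- ut[order(ut[, 2L], ut[, 1L]), , drop = FALSE]
    for (r in seq_len(nut)) {
      theta[r] <- if (ut[r, 1L] == ut[r, 2L]) exp(par[r]) else par[r]
    }
    theta[nut + seq_len(K)] <- exp(par[nut + seq_len(K)])
    -oracle_reml_logL(theta, y, blk, A)
  }
  vy <- stats::var(y)
  best <- NULL
  for (f in c(0.5, 0.2, 0.8)) {
    start <- numeric(nut + K)
    ut <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
    ut <- ut[order(ut[, 2L], ut[, 1L]), , drop = FALSE]
    for (r in seq_len(nut)) {
      start[r] <- if (ut[r, 1L] == ut[r, 2L]) log(f * vy) else 0.1 * vy
    }
    start[nut + seq_len(K)] <- log((1 - f) * vy)
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ut <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 2L], ut[, 1L]), , drop = FALSE]
  theta <- numeric(nut + K)
  for (r in seq_len(nut)) {
    theta[r] <- if (ut[r, 1L] == ut[r, 2L]) exp(best$par[r]) else best$par[r]
  }
  theta[nut + seq_len(K)] <- exp(best$par[nut + seq_len(K)])
  list(theta = theta, logL = -best$value)
}

# quick two-group G x E dataset with known architecture; returns the
# cohort, the GRM and the genotypes
sim_gxe_data <- function(n_per_group, m, h2, rg, seed,
                         covariates = NULL) {
  g <- simulate_genotypes(sum(n_per_group), m, seed = seed)
  K <- length(n_per_group)
  R <- matrix(rg, K, K); diag(R) <- 1
  sg <- R * tcrossprod(sqrt(h2))
  coh <- simulate_gxe_cohort(g, n_per_group, sg, 1 - h2,
                             covariates = covariates, seed = seed + 1000L)
  list(cohort = coh, grm = compute_grm(g), genotypes = g)
}
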