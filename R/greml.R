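#' Multivariate GREML: genetic (co)variance across groups or traits
#'
#' Fits the multivariate genomic REML model in which phenotype vectors
#' `y_i = X_i b_i + Z_i g_i + e_i` for `K` blocks (environment groups, or
#' traits) share additive genetic effects tagged by one or more genomic
#' relationship matrices.  The phenotypic covariance of the stacked data is
#' \deqn{V = \sum_m A_m \circ \Sigma_g^{(m)}[blk, blk] + E,}
#' i.e. block `(i, j)` of `V` is `A sigma_g_ij` plus, on matching
#' observations, the residual term.  Two residual structures are supported:
#' \describe{
#'   \item{`"gxe"`}{blocks hold disjoint individuals measured in different
#'     environments; residual covariances are structurally zero (no
#'     individual has repeated measures) and only the per-block residual
#'     variances are estimated.}
#'   \item{`"multi_trait"`}{blocks are traits that may be measured on the
#'     same individuals; residual covariances between blocks are estimated
#'     for individuals shared between them (omitting them would inflate the
#'     genetic covariance).}
#' }
#'
#' Estimation is average-information REML: starting from
#' `sigma_g = sigma_e = var(y_i)/2` per block, one expectation-maximization
#' warm-up step is followed by Newton steps using the average-information
#' matrix, with step-halving whenever a step would decrease the restricted
#' likelihood and flooring of variances at `floor_frac * var(y_i)`.
#' Covariances are unconstrained, so genetic correlations above 1 in
#' magnitude are representable.  Convergence is declared when the
#' restricted log-likelihood changes by less than `tol`.
#'
#' `greml()` is the data-frame front end (`phenotype ~ group`);
#' `greml_fit()` is the vector-level engine.
#'
#' @param formula A two-sided formula `phenotype ~ group`.
#' @param data A cohort `data.frame` holding the formula variables and a
#'   `sample_id` column matching the GRM sample IDs.
#' @param y Numeric phenotype vector (one element per observation).
#' @param groups Factor (or coercible) assigning each observation to a
#'   block.
#' @param grm A `"grm"` object, or a (optionally named) list of them for a
#'   multi-component fit partitioning the genetic variance.
#' @param ids Sample IDs linking observations to GRM samples; defaults to
#'   `names(y)`.
#' @param mode Residual structure, `"gxe"` or `"multi_trait"` (see above).
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood (default `1e-6`).
#' @param max_iter Maximum AI iterations (default 100).
#' @param floor_frac Variance floor as a fraction of the block phenotypic
#'   variance (default `1e-6`).
#' @param info_type `"average"` (the AI matrix at convergence, the default)
#'   or `"observed"` (the observed information, recomputed at the optimum)
#'   as the basis of `vcov()` and all delta-method standard errors.
#' @param verbose Print the likelihood trail while iterating.
#' @return An object of class `"greml"` with components `sigma_g` (list of
#'   K x K genetic covariance matrices, one per GRM), `sigma_e` (K x K
#'   residual covariance matrix; diagonal in `"gxe"` mode), `theta`,
#'   `param_table`, `logL`, `logL_trail`, `info`, `vcov`, `converged`,
#'   `n_iter`, `boundary`, `identifiable`, `groups`, `n_per_group`.
#'   Non-convergence raises a condition of class
#'   `"greml_convergence_error"` carrying the likelihood trail.
#' @examples
#' g <- simulate_genotypes(400, 300, seed = 1)
#' sg <- matrix(c(0.3, 0.18, 0.18, 0.3), 2)
#' coh <- simulate_gxe_cohort(g, c(200, 200), sg, c(0.7, 0.7),
#'                            covariates = NULL, seed = 2)
#' A <- compute_grm(g)
#' fit <- greml(phenotype ~ group, coh, A)
#' summary(fit)
#' @seealso [genetic_correlation()], [gxe_scan()], [partition_ratio()]
#' @export
greml <- function(formula, data, grm, mode = c("gxe", "multi_trait"), ...) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- mf[[1L]]
  groups <- mf[[2L]]
  ids <- if ("sample_id" %in% names(data)) data$sample_id else rownames(data)
  ok <- is.finite(y) & !is.na(groups)
  greml_fit(y[ok], groups[ok], grm, ids = ids[ok], mode = mode, ...)
}

#' @rdname greml
#' @export
greml_fit <- function(y, groups, grm, ids = NULL,
                      mode = c("gxe", "multi_trait"),
                      tol = 1e-6, max_iter = 100L, floor_frac = 1e-6,
                      info_type = c("average", "observed"), verbose = FALSE) {
  mode <- match.arg(mode)
  info_type <- match.arg(info_type)
  grms <- if (inherits(grm, "grm")) list(grm) else grm
  if (!length(grms) || !all(vapply(grms, inherits, TRUE, "grm"))) {
    stop("'grm' must be a grm object or a list of them")
  }
  if (is.null(names(grms))) names(grms) <- paste0("grm", seq_along(grms))
  y <- as.numeric(y)
  N <- length(y)
  groups <- droplevels(as.factor(groups))
  K <- nlevels(groups)
  lev <- levels(groups)
  if (length(groups) != N) stop("'y' and 'groups' lengths differ")
  if (is.null(ids)) ids <- names(y)
  if (is.null(ids)) stop("'ids' is required to link observations to the GRM")
  ids <- as.character(ids)
  blk <- as.integer(groups)
  idx <- split(seq_len(N), blk)
  n_per_group <- lengths(idx)
  if (any(n_per_group < 2L)) stop("every block needs at least 2 observations")
  if (mode == "gxe" && anyDuplicated(ids)) {
    stop("duplicate sample IDs are not allowed in 'gxe' mode ",
         "(each individual belongs to exactly one environment)")
  }
  for (k in seq_len(K)) {
    if (anyDuplicated(ids[idx[[k]]])) {
      stop("duplicate sample IDs within block ", lev[k])
    }
  }
  Asub <- lapply(grms, function(g) {
    pos <- match(ids, g$samples)
    if (anyNA(pos)) {
      stop("sample IDs absent from GRM: ",
           paste(utils::head(ids[is.na(pos)], 3L), collapse = ", "), " ...")
    }
    g$values[pos, pos, drop = FALSE]
  })

  # parameter layout: genetic (co)variances per GRM, then residuals
  pt <- do.call(rbind, c(
    lapply(seq_along(grms), function(m) {
      ij <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
      data.frame(type = "g", grm = m, i = ij[, 1L], j = ij[, 2L])
    }),
    list(data.frame(type = "e", grm = 0L, i = seq_len(K), j = seq_len(K)))
  ))
  epairs <- list()
  if (mode == "multi_trait" && K > 1L) {
    for (i in seq_len(K - 1L)) for (j in seq(i + 1L, K)) {
      pos <- match(ids[idx[[i]]], ids[idx[[j]]])
      hit <- which(!is.na(pos))
      if (length(hit)) {
        epairs[[paste(i, j)]] <- cbind(idx[[i]][hit], idx[[j]][pos[hit]])
        pt <- rbind(pt, data.frame(type = "e", grm = 0L, i = i, j = j))
      }
    }
  }
  pt$name <- ifelse(pt$type == "g",
    paste0("Vg", if (length(grms) > 1L) pt$grm else "", "(",
           lev[pt$i], ifelse(pt$i == pt$j, "", paste0(",", lev[pt$j])), ")"),
    paste0("Ve(", lev[pt$i],
           ifelse(pt$i == pt$j, "", paste0(",", lev[pt$j])), ")"))
  p <- nrow(pt)

  vy <- vapply(idx, function(r) stats::var(y[r]), 0)
  floor_val <- floor_frac * vy
  theta <- numeric(p)
  for (k in seq_len(p)) {
    theta[k] <- if (pt$type[k] == "g") {
      if (pt$i[k] == pt$j[k]) vy[pt$i[k]] / (2 * length(grms))
      else 0.5 * sqrt(vy[pt$i[k]] * vy[pt$j[k]]) / (2 * length(grms))
    } else if (pt$i[k] == pt$j[k]) vy[pt$i[k]] / 2 else 0
  }

  X <- matrix(0, N, K, dimnames = list(NULL, lev))
  X[cbind(seq_len(N), blk)] <- 1

  build_V <- function(th) {
    V <- matrix(0, N, N)
    for (m in seq_along(grms)) {
      Sg <- matrix(0, K, K)
      gm <- pt$type == "g" & pt$grm == m
      Sg[cbind(pt$i[gm], pt$j[gm])] <- th[gm]
      Sg[cbind(pt$j[gm], pt$i[gm])] <- th[gm]
      V <- V + Asub[[m]] * Sg[blk, blk, drop = FALSE]
    }
    ed <- pt$type == "e" & pt$i == pt$j
    dvec <- th[ed][blk]
    diag(V) <- diag(V) + dvec
    eo <- which(pt$type == "e" & pt$i != pt$j)
    for (k in eo) {
      pr <- epairs[[paste(pt$i[k], pt$j[k])]]
      V[pr] <- V[pr] + th[k]
      V[pr[, 2:1, drop = FALSE]] <- V[pr[, 2:1, drop = FALSE]] + th[k]
    }
    V
  }

  eval_theta <- function(th) {
    V <- build_V(th)
    C <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(C)) return(NULL)
    Vi <- chol2inv(C)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cx)) return(NULL)
    XtViX_inv <- chol2inv(cx)
    Viy <- Vi %*% y
    beta <- XtViX_inv %*% crossprod(ViX, y)
    Py <- Viy - ViX %*% beta
    logL <- -0.5 * (2 * sum(log(diag(C))) + 2 * sum(log(diag(cx))) +
                    sum(y * Py) + (N - K) * log(2 * pi))
    list(logL = logL, Vi = Vi, ViX = ViX, XtViX_inv = XtViX_inv,
         Py = as.numeric(Py))
  }

  # t_k = dV_k %*% v for parameter k
  dV_mult <- function(k, v) {
    out <- numeric(N)
    if (pt$type[k] == "g") {
      ri <- idx[[pt$i[k]]]; ci <- idx[[pt$j[k]]]
      Am <- Asub[[pt$grm[k]]]
      if (pt$i[k] == pt$j[k]) {
        out[ri] <- Am[ri, ri, drop = FALSE] %*% v[ri]
      } else {
        B <- Am[ri, ci, drop = FALSE]
        out[ri] <- B %*% v[ci]
        out[ci] <- crossprod(B, v[ri])
      }
    } else if (pt$i[k] == pt$j[k]) {
      ri <- idx[[pt$i[k]]]
      out[ri] <- v[ri]
    } else {
      pr <- epairs[[paste(pt$i[k], pt$j[k])]]
      out[pr[, 1L]] <- out[pr[, 1L]] + v[pr[, 2L]]
      out[pr[, 2L]] <- out[pr[, 2L]] + v[pr[, 1L]]
    }
    out
  }

  trace_P_dV <- function(k, P, dP) {
    if (pt$type[k] == "g") {
      ri <- idx[[pt$i[k]]]; ci <- idx[[pt$j[k]]]
      Am <- Asub[[pt$grm[k]]]
      s <- sum(P[ri, ci, drop = FALSE] * Am[ri, ci, drop = FALSE])
      if (pt$i[k] != pt$j[k]) s <- 2 * s
      s
    } else if (pt$i[k] == pt$j[k]) {
      sum(dP[idx[[pt$i[k]]]])
    } else {
      2 * sum(P[epairs[[paste(pt$i[k], pt$j[k])]]])
    }
  }

  apply_floor <- function(th) {
    for (k in seq_len(p)) {
      if (pt$i[k] == pt$j[k]) {
        fl <- floor_val[pt$i[k]]
        if (th[k] < fl) th[k] <- fl
      }
    }
    th
  }
  theta <- apply_floor(theta)

  ev <- eval_theta(theta)
  if (is.null(ev)) stop("starting values give a singular covariance matrix")
  trail <- ev$logL
  converged <- FALSE
  singular_info <- FALSE
  it <- 0L

  ai_score <- function(ev) {
    P <- ev$Vi - ev$ViX %*% tcrossprod(ev$XtViX_inv, ev$ViX)
    dP <- diag(P)
    Tm <- vapply(seq_len(p), function(k) dV_mult(k, ev$Py), numeric(N))
    PT <- P %*% Tm
    AI <- 0.5 * crossprod(Tm, PT)
    AI <- (AI + t(AI)) / 2
    tr <- vapply(seq_len(p), function(k) trace_P_dV(k, P, dP), 0)
    yPdPy <- as.numeric(crossprod(ev$Py, Tm))
    list(AI = AI, score = -0.5 * (tr - yPdPy), yPdPy = yPdPy, tr = tr,
         P = P)
  }

  while (it < max_iter) {
    it <- it + 1L
    as_ <- ai_score(ev)
    if (it == 1L) {
      delta <- theta^2 * (as_$yPdPy - as_$tr) / N
    } else {
      delta <- tryCatch(solve(as_$AI, as_$score), error = function(e) NULL)
      if (is.null(delta)) {
        singular_info <- TRUE
        delta <- as_$score / pmax(abs(diag(as_$AI)), 1e-8)
      }
    }
    step <- 1
    accepted <- FALSE
    for (h in 1:30) {
      cand <- apply_floor(theta + step * delta)
      evc <- eval_theta(cand)
      if (!is.null(evc) && evc$logL >= ev$logL - 1e-10) {
        dl <- evc$logL - ev$logL
        theta <- cand; ev <- evc
        trail <- c(trail, evc$logL)
        accepted <- TRUE
        if (verbose) {
          cat(sprintf("iter %2d logL %.6f (step %.3g)\n", it, evc$logL, step))
        }
        if (abs(dl) < tol) converged <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      # no uphill step available at any step length: at a (possibly
      # floored) optimum
      converged <- TRUE
    }
    if (converged) break
  }

  if (!converged) {
    cond <- structure(
      class = c("greml_convergence_error", "error", "condition"),
      list(message = paste0("AI-REML did not converge in ", max_iter,
                            " iterations (last logL ",
                            format(utils::tail(trail, 1L)), ")"),
           call = sys.call(-1L), trail = trail))
    stop(cond)
  }

  final <- ai_score(ev)
  info <- final$AI
  if (info_type == "observed") {
    info <- .observed_info(final$P, ev$Py, p, dV_mult)
  }
  dimnames(info) <- list(pt$name, pt$name)
  boundary <- vapply(seq_len(p), function(k) {
    pt$i[k] == pt$j[k] && theta[k] <= floor_val[pt$i[k]] * (1 + 1e-8)
  }, TRUE)
  rc <- rcond(info)
  identifiable <- is.finite(rc) && rc > 1e-10 && !singular_info
  vc <- if (identifiable) {
    v <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(v)) { identifiable <- FALSE; NULL } else v
  } else NULL
  if (is.null(vc)) {
    vc <- matrix(NA_real_, p, p, dimnames = dimnames(info))
  }

  sigma_g <- lapply(seq_along(grms), function(m) {
    Sg <- matrix(0, K, K, dimnames = list(lev, lev))
    gm <- pt$type == "g" & pt$grm == m
    Sg[cbind(pt$i[gm], pt$j[gm])] <- theta[gm]
    Sg[cbind(pt$j[gm], pt$i[gm])] <- theta[gm]
    Sg
  })
  names(sigma_g) <- names(grms)
  Se <- matrix(0, K, K, dimnames = list(lev, lev))
  em <- pt$type == "e"
  Se[cbind(pt$i[em], pt$j[em])] <- theta[em]
  Se[cbind(pt$j[em], pt$i[em])] <- theta[em]

  structure(list(
    sigma_g = sigma_g, sigma_e = Se,
    theta = stats::setNames(theta, pt$name), param_table = pt,
    logL = ev$logL, logL_trail = trail, info = info, vcov = vc,
    converged = TRUE, n_iter = it, boundary = boundary,
    identifiable = identifiable, mode = mode, info_type = info_type,
    groups = lev, n_per_group = stats::setNames(as.integer(n_per_group), lev),
    N = N, floor = stats::setNames(floor_val, lev),
    call = match.call()
  ), class = "greml")
}

# observed information -E[d2 logL] evaluated at the data:
# O_kl = y' P dV_k P dV_l P y - 0.5 tr(P dV_k P dV_l)
.observed_info <- function(P, Py, p, dV_mult) {
  N <- length(Py)
  # build P dV_k columnwise through the matvec representation
  PdV <- lapply(seq_len(p), function(k) {
    M <- vapply(seq_len(N), function(cc) {
      v <- numeric(N); v[cc] <- 1
      dV_mult(k, v)
    }, numeric(N))
    P %*% M
  })
  O <- matrix(0, p, p)
  for (k in seq_len(p)) {
    tk <- dV_mult(k, Py)
    for (l in k:p) {
      tl <- dV_mult(l, Py)
      quad <- sum(tk * (P %*% tl))
      # y'P dVk P dVl P y with the middle P: tk' P tl
      O[k, l] <- O[l, k] <- quad - 0.5 * sum(PdV[[k]] * t(PdV[[l]]))
    }
  }
  O
}

#' @export
print.greml <- function(x, digits = 4, ...) {
  cat("Multivariate GREML fit (", x$mode, " mode): ", length(x$groups),
      " block(s), N = ", x$N, "\n", sep = "")
  cat("  logL =", format(x$logL, digits = 8), "after", x$n_iter,
      "iterations;", if (x$converged) "converged" else "NOT converged", "\n")
  cat("Variance components:\n")
  print(round(x$theta, digits))
  if (any(x$boundary)) {
    cat("Boundary: ", paste(names(x$theta)[x$boundary], collapse = ", "),
        " at the variance floor\n", sep = "")
  }
  if (!x$identifiable) {
    cat("Warning: information matrix is singular; standard errors are",
        "not available (non-identifiable model)\n")
  }
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) object$theta

#' @export
vcov.greml <- function(object, ...) object$vcov

#' @export
logLik.greml <- function(object, ...) {
  structure(object$logL, df = length(object$theta), class = "logLik")
}

#' @export
summary.greml <- function(object, ...) {
  h2 <- h2_estimates(object)
  K <- length(object$groups)
  rg <- NULL
  if (K > 1L) {
    pairs <- which(upper.tri(diag(K)), arr.ind = TRUE)
    rg <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      gc <- tryCatch(
        genetic_correlation(object, pairs[r, 1L], pairs[r, 2L]),
        error = function(e) NULL)
      if (is.null(gc)) return(NULL)
      data.frame(group_i = object$groups[pairs[r, 1L]],
                 group_j = object$groups[pairs[r, 2L]],
                 r_g = gc$r_g, se = gc$se,
                 p_vs_0 = gc$p_vs_0, p_vs_1 = gc$p_vs_1)
    }))
  }
  structure(list(h2 = h2, r_g = rg, fit = object), class = "summary.greml")
}

#' @export
print.summary.greml <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nSNP-heritability per block:\n")
  print(format(x$h2, digits = digits), quote = FALSE)
  if (!is.null(x$r_g)) {
    cat("\nGenetic correlations:\n")
    print(format(x$r_g, digits = digits), quote = FALSE)
  }
  invisible(x)
}

#' Per-block SNP-heritability estimates from a GREML fit
#'
#' `h2_i = sum_m sigma_g_m[i,i] / (sum_m sigma_g_m[i,i] + sigma_e[i,i])`,
#' with delta-method standard errors from the inverse information matrix
#' and a two-sided Wald p-value against zero.
#'
#' @param fit A `"greml"` fit.
#' @return A `data.frame` with one row per block: `group`, `h2`, `se`, `p`.
#' @export
h2_estimates <- function(fit) {
  stopifnot(inherits(fit, "greml"))
  pt <- fit$param_table
  K <- length(fit$groups)
  out <- lapply(seq_len(K), function(i) {
    gk <- which(pt$type == "g" & pt$i == i & pt$j == i)
    ek <- which(pt$type == "e" & pt$i == i & pt$j == i)
    G <- sum(fit$theta[gk]); E <- fit$theta[ek]
    tot <- G + E
    h2 <- G / tot
    grad <- numeric(length(fit$theta))
    grad[gk] <- E / tot^2
    grad[ek] <- -G / tot^2
    v <- if (fit$identifiable) drop(t(grad) %*% fit$vcov %*% grad)
         else NA_real_
    se <- if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
    data.frame(group = fit$groups[i], h2 = h2, se = se,
               p = if (is.finite(se) && se > 0) wald_test(h2, se, 0)
                   else NA_real_)
  })
  do.call(rbind, out)
}
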