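#' Truncated-selection theory for genetic correlations
#'
#' Closed-form moments of a standard-normal trait, and of its additive
#' genetic value, after interval truncation selection -- either directly on
#' the trait or on an environmental variable correlated with it.  The
#' central result is that the cross-group genetic correlation is invariant
#' under such selection, so stratifying a cohort by a phenotype-correlated
#' environmental exposure does not by itself create spurious
#' genotype-by-environment interaction.
#'
#' The trait is modelled as y = g + e with y ~ N(0, 1),
#' g ~ N(0, h2) and e ~ N(0, 1 - h2).  Selection retains individuals whose
#' selection variable falls in the interval (t1, t2); `K1` and `K2` are the
#' upper-tail proportions beyond `t1` and `t2`, and the selection
#' intensities are i_j = phi(t_j) / K_j.
#'
#' @param t1,t2 Truncation thresholds on the standard-normal scale,
#'   `t1 < t2`; `-Inf` / `Inf` are allowed and recover the no-selection
#'   limit.
#' @param h2 Heritability of the trait, in `[0, 1]`.
#' @param r Correlation between the trait and the selection variable
#'   (`r = 1` for direct selection on the trait itself).
#' @return `selection_regime()` returns an object of class
#'   `"selection_regime"`: a list with `t1`, `t2`, `K1`, `K2`, `i1`, `i2`,
#'   `h2` and `r`.
#' @examples
#' reg <- selection_regime(-1, 1, h2 = 0.5)
#' post_selection_moments(reg)
#' @seealso [post_selection_moments()], [correlated_selection_moments()],
#'   [rg_under_selection()]
#' @export
selection_regime <- function(t1, t2, h2, r = 1) {
  stopifnot(is.numeric(t1), is.numeric(t2), length(t1) == 1L, length(t2) == 1L)
  if (!(t1 < t2)) {
    stop("selection thresholds must satisfy t1 < t2 (got ", t1, " >= ", t2, ")")
  }
  if (!is.numeric(h2) || length(h2) != 1L || h2 < 0 || h2 > 1) {
    stop("'h2' must be a single value in [0, 1]")
  }
  if (!is.numeric(r) || length(r) != 1L || abs(r) > 1) {
    stop("'r' must be a single correlation in [-1, 1]")
  }
  ki <- truncation_constants(t1, t2)
  structure(
    list(t1 = t1, t2 = t2, K1 = ki$K1, K2 = ki$K2, i1 = ki$i1, i2 = ki$i2,
         h2 = h2, r = r),
    class = "selection_regime"
  )
}

#' @export
print.selection_regime <- function(x, ...) {
  cat("Truncation selection regime: keep", format(x$t1), "< s <", format(x$t2), "\n")
  cat(sprintf("  selected proportion %.4f, h2 = %.3f, r = %.3f\n",
              x$K1 - x$K2, x$h2, x$r))
  invisible(x)
}

#' Upper-tail proportions and selection intensities at truncation thresholds
#'
#' For thresholds on the standard-normal scale, computes the upper-tail
#' proportion K = 1 - Phi(t) and the selection intensity i = phi(t) / K.
#' At infinite thresholds the limit conventions K * i -> 0 and
#' K * i * t -> 0 apply (the products, not `i` itself, enter every moment
#' formula).
#'
#' @inheritParams selection_regime
#' @return A list with `K1`, `K2`, `i1`, `i2`.
#' @examples
#' truncation_constants(0, Inf)  # K1 = 0.5, i1 = 0.7978846
#' @export
truncation_constants <- function(t1, t2) {
  if (!(t1 < t2)) stop("truncation thresholds must satisfy t1 < t2")
  K1 <- stats::pnorm(t1, lower.tail = FALSE)
  K2 <- stats::pnorm(t2, lower.tail = FALSE)
  i1 <- if (K1 > 0) stats::dnorm(t1) / K1 else Inf
  i2 <- if (K2 > 0) stats::dnorm(t2) / K2 else Inf
  list(K1 = K1, K2 = K2, i1 = i1, i2 = i2)
}

# Shared building blocks for the interval (t1, t2):
#   D = K2 - K1            (minus the selected proportion)
#   S = K2 i2 - K1 i1      = phi(t2) - phi(t1)
#   Tt = K2 i2 t2 - K1 i1 t1 = t2 phi(t2) - t1 phi(t1)
# with x * phi(x) -> 0 at +/- Inf.
.trunc_blocks <- function(t1, t2) {
  xphi <- function(t) if (is.finite(t)) t * stats::dnorm(t) else 0
  D <- stats::pnorm(t2, lower.tail = FALSE) - stats::pnorm(t1, lower.tail = FALSE)
  if (abs(D) < .Machine$double.eps) {
    stop("degenerate selection region: selected proportion is zero")
  }
  list(D = D,
       S = stats::dnorm(t2) - stats::dnorm(t1),
       Tt = xphi(t2) - xphi(t1))
}

.selection_moments <- function(t1, t2, h2, r) {
  b <- .trunc_blocks(t1, t2)
  ratio_T <- b$Tt / b$D            # E(y_s^2) - 1 under direct selection
  ratio_S <- b$S / b$D             # E(y_s) under direct selection
  kappa <- ratio_S^2 - ratio_T     # variance reduction 1 - var(y_s | r = 1)

  mean_y <- r * ratio_S
  var_y <- 1 - r^2 * kappa
  mean_g <- h2 * mean_y
  e_g2 <- h2 * (1 + h2 * r^2 * ratio_T)
  var_g <- h2 * (1 - h2 * r^2 * kappa)
  moments <- list(
    mean_y = mean_y,
    var_y = var_y,
    e_y2 = 1 + r^2 * ratio_T,
    mean_g = mean_g,
    e_g2 = e_g2,
    var_g = var_g,
    h2_s = var_g / var_y,
    b = sqrt(1 - h2 * r^2 * kappa),
    c = mean_g,
    t1 = t1, t2 = t2, h2 = h2, r = r
  )
  class(moments) <- "selection_moments"
  moments
}

#' Post-selection moments under direct truncation selection
#'
#' Evaluates the closed-form mean and variance of the phenotype and of the
#' genetic value after retaining the interval `t1 < y < t2` of a standard
#' normal trait, together with the post-selection heritability
#' `h2_s = var(g_s) / var(y_s)` and the scale factor `b` of the linear
#' representation `g_s = c + b g` of the selected genetic values.  Selection
#' on the phenotype shrinks the genetic variance by the factor
#' `1 - h2 * (1 - var(y_s))` -- less than the shrinkage of the phenotypic
#' variance itself, because truncation also induces a negative correlation
#' between genetic and residual deviations in the survivors.  The variance
#' ratio `h2_s` therefore *exceeds* `h2` for interior intervals and can
#' exceed 1; the cross-group genetic correlation, meanwhile, is untouched
#' (see [rg_under_selection()]).
#'
#' @param regime A [selection_regime()] with `r = 1`.
#' @return An object of class `"selection_moments"`: a list with `mean_y`,
#'   `var_y`, `e_y2`, `mean_g`, `e_g2`, `var_g`, `h2_s`, `b` and `c`
#'   (the intercept of `g_s = c + b g`, equal to `mean_g`).
#' @examples
#' post_selection_moments(selection_regime(-1, 1, h2 = 0.5))
#' @export
post_selection_moments <- function(regime) {
  stopifnot(inherits(regime, "selection_regime"))
  if (regime$r != 1) {
    stop("post_selection_moments() is for direct selection (r = 1); ",
         "use correlated_selection_moments() for r < 1")
  }
  .selection_moments(regime$t1, regime$t2, regime$h2, r = 1)
}

#' Post-selection moments under selection on a correlated variable
#'
#' Moments of the trait and of its genetic value when the truncation
#' interval is applied not to the trait itself but to an environmental
#' variable with phenotypic correlation `r` to it, modelled jointly as
#' bivariate standard normal.  The canonical outputs are the exact moments,
#' which reduce to the direct-selection case at `r = 1` and are what a
#' Monte-Carlo simulation of the bivariate model reproduces:
#' `E(g_s) = h2 * E(y_s)` and
#' `var(g_s) = h2 * (1 - h2 * r^2 * (1 - var(y_s; r = 1)))`.
#'
#' A published variant of this algebra sets `E(g_s) = 0` (on the argument
#' that the environmental variable has no genetic basis) while keeping the
#' second moment of the correlated model, and consequently omits the
#' `E(g_s)^2` term from `var(g_s)`.  Those quantities are returned as
#' `mean_g_printed`, `var_g_printed`, `h2_s_printed` and `b_printed` for
#' comparison; the two versions coincide exactly when the truncation
#' interval is symmetric about zero (where `E(y_s) = 0`).  Either way the
#' cross-group genetic correlation is unaffected by the selection.
#'
#' @param regime A [selection_regime()] (any `r` in `[-1, 1]`).
#' @return A `"selection_moments"` list as in [post_selection_moments()],
#'   with additional `mean_g_printed`, `var_g_printed`, `h2_s_printed`,
#'   `b_printed` fields.
#' @examples
#' correlated_selection_moments(selection_regime(-0.5, 1.5, h2 = 0.3, r = 0.6))
#' @export
correlated_selection_moments <- function(regime) {
  stopifnot(inherits(regime, "selection_regime"))
  m <- .selection_moments(regime$t1, regime$t2, regime$h2, regime$r)
  # variant with E(g_s) forced to zero: var(g_s) collapses to E(g_s^2)
  m$mean_g_printed <- 0
  m$var_g_printed <- m$e_g2
  m$h2_s_printed <- m$e_g2 / m$var_y
  m$b_printed <- if (regime$h2 > 0) sqrt(m$e_g2 / regime$h2) else 1
  m
}

#' @export
print.selection_moments <- function(x, digits = 4, ...) {
  cat("Post-selection moments (interval", format(x$t1), "<", "s", "<",
      format(x$t2), paste0("; h2 = ", format(x$h2), ", r = ", format(x$r)),
      ")\n")
  tab <- c(`E(y_s)` = x$mean_y, `var(y_s)` = x$var_y,
           `E(g_s)` = x$mean_g, `var(g_s)` = x$var_g,
           `h2_s` = x$h2_s, b = x$b)
  print(round(tab, digits))
  invisible(x)
}

#' Genetic correlation between two truncation-selected groups
#'
#' The invariance identity: selected genetic values in each group satisfy
#' `g_s = c + b g`, so
#' `cor(g_s1, g_s2) = b1 b2 cov(g1, g2) / (b1 sd(g1) b2 sd(g2)) =
#' cor(g1, g2)` -- the genetic correlation between two environmentally
#' selected groups equals the unselected one, whatever the truncation
#' regimes.  Returned alongside the two `b` factors for reporting.
#'
#' @param r_g True (pre-selection) genetic correlation, `|r_g| <= 1`.
#' @param regime_1,regime_2 [selection_regime()] objects for the two groups.
#' @return A list with `r_g` (unchanged), `b1` and `b2`.
#' @examples
#' rg_under_selection(0.6, selection_regime(-1, 0.5, h2 = 0.3),
#'                    selection_regime(0, Inf, h2 = 0.3))
#' @export
rg_under_selection <- function(r_g, regime_1, regime_2) {
  if (!is.numeric(r_g) || length(r_g) != 1L || abs(r_g) > 1) {
    stop("'r_g' must be a single correlation in [-1, 1]")
  }
  b1 <- .selection_moments(regime_1$t1, regime_1$t2, regime_1$h2, regime_1$r)$b
  b2 <- .selection_moments(regime_2$t1, regime_2$t2, regime_2$h2, regime_2$r)$b
  list(r_g = r_g, b1 = b1, b2 = b2)
}
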