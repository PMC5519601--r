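#' Adjust a phenotype for fixed covariates by linear regression
#'
#' Regresses the raw phenotype on an intercept plus the supplied covariate
#' columns by ordinary least squares and returns the residuals -- the
#' standard pre-adjustment for confounders (year of birth, age, sex,
#' assessment centre, genotyping batch, ancestry principal components, ...)
#' before variance-component analysis.  Rows with missing phenotype or
#' covariates are dropped from the fit and returned as `NA`; collinear
#' (aliased) design columns are dropped with a warning naming them.
#'
#' @param y Numeric raw phenotype.
#' @param covariates Optional `data.frame` (factors allowed) with one row
#'   per element of `y`; `NULL` adjusts for the intercept only (mean
#'   centering).
#' @return Numeric vector of OLS residuals, `NA` where input rows were
#'   dropped, with attributes `n_dropped` and `aliased` (names of dropped
#'   design columns).
#' @examples
#' x <- rnorm(100)
#' y <- 2 * x + rnorm(100)
#' r <- adjust_phenotype(y, data.frame(x = x))
#' abs(cor(r, x)) < 1e-10
#' @export
adjust_phenotype <- function(y, covariates = NULL) {
  n <- length(y)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    ok <- is.finite(y)
    out <- rep(NA_real_, n)
    out[ok] <- y[ok] - mean(y[ok])
    attr(out, "n_dropped") <- sum(!ok)
    attr(out, "aliased") <- character()
    return(out)
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) {
    stop("'covariates' must have one row per phenotype value")
  }
  ok <- is.finite(y) & stats::complete.cases(covariates)
  X <- stats::model.matrix(~ ., data = covariates[ok, , drop = FALSE])
  if (sum(ok) <= ncol(X)) {
    stop("fewer observations (", sum(ok), ") than design columns (",
         ncol(X), ") after dropping missing rows")
  }
  fit <- stats::lm.fit(X, y[ok])
  aliased <- names(fit$coefficients)[is.na(fit$coefficients)]
  if (length(aliased)) {
    warning("dropping aliased design column(s): ",
            paste(aliased, collapse = ", "))
  }
  out <- rep(NA_real_, n)
  out[ok] <- fit$residuals
  attr(out, "n_dropped") <- sum(!ok)
  attr(out, "aliased") <- aliased
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values onto standard-normal quantiles via the Blom offset:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties assigned their average
#' rank.  The transform is invariant to any monotone transformation of the
#' input and preserves input ordering; `NA`s pass through.
#'
#' @param values Numeric vector, at least two finite non-identical values.
#' @return Transformed vector of the same length.
#' @examples
#' inverse_normal_transform(c(3, 1, 4, 1, 5))
#' @export
inverse_normal_transform <- function(values) {
  ok <- is.finite(values)
  x <- values[ok]
  if (length(x) < 2L) stop("need at least two finite values")
  if (max(x) == min(x)) stop("all values identical; transform is degenerate")
  n <- length(x)
  z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

#' Stratify a cohort into environment groups
#'
#' Assigns each sample to one environment group from its binary early-life
#' exposure labels (`breastfed`, `maternal_smoking`, each
#' `yes`/`no`/`unknown`); samples with an unknown or missing label are
#' excluded from every mode.  Modes:
#' \describe{
#'   \item{four_group}{the exposure cross `B&NS`, `B&S`, `NB&NS`, `NB&S`
#'     (B = breastfed, S = maternal smoking);}
#'   \item{breastfeeding_only}{`B` vs `NB`;}
#'   \item{smoking_only}{`NS` vs `S`;}
#'   \item{eight_group_by_sex}{the four-way cross split further by the
#'     `sex` column (`M`/`F`), e.g. `B&NS_M`.}
#' }
#'
#' @param cohort Cohort `data.frame` with `breastfed` and
#'   `maternal_smoking` columns (and `sex` for the by-sex mode).
#' @param mode Stratification mode; see above.
#' @param min_group Warn when any group is smaller than this floor
#'   (default 50).
#' @return The retained subset of `cohort` with a `group` factor column;
#'   group sizes in `attr(, "group_sizes")`, number of excluded samples in
#'   `attr(, "n_excluded")`.
#' @examples
#' coh <- data.frame(sample_id = 1:6,
#'                   breastfed = c("yes", "yes", "no", "no", "unknown", "yes"),
#'                   maternal_smoking = c("no", "yes", "no", "yes", "no", "no"))
#' table(stratify(coh, min_group = 1)$group)
#' @export
stratify <- function(cohort,
                     mode = c("four_group", "breastfeeding_only",
                              "smoking_only", "eight_group_by_sex"),
                     min_group = 50) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cohort))
  need <- c("breastfed", "maternal_smoking")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have 'breastfed' and 'maternal_smoking' columns")
  }
  bin <- function(x) {
    x <- tolower(as.character(x))
    ifelse(x %in% c("yes", "no"), x, NA_character_)
  }
  bf <- bin(cohort$breastfed)
  sm <- bin(cohort$maternal_smoking)
  four <- paste0(ifelse(bf == "yes", "B", "NB"), "&",
                 ifelse(sm == "yes", "S", "NS"))
  four[is.na(bf) | is.na(sm)] <- NA
  grp <- switch(mode,
    four_group = four,
    breastfeeding_only = ifelse(is.na(bf), NA,
                                ifelse(bf == "yes", "B", "NB")),
    smoking_only = ifelse(is.na(sm), NA,
                          ifelse(sm == "yes", "S", "NS")),
    eight_group_by_sex = {
      if (!"sex" %in% names(cohort)) {
        stop("by-sex stratification needs a 'sex' column")
      }
      sex <- toupper(as.character(cohort$sex))
      sex[!sex %in% c("M", "F")] <- NA
      ifelse(is.na(four) | is.na(sex), NA, paste0(four, "_", sex))
    })
  levels_order <- switch(mode,
    four_group = c("B&NS", "B&S", "NB&NS", "NB&S"),
    breastfeeding_only = c("B", "NB"),
    smoking_only = c("NS", "S"),
    eight_group_by_sex = as.vector(t(outer(
      c("B&NS", "B&S", "NB&NS", "NB&S"), c("M", "F"), paste, sep = "_"))))
  keep <- !is.na(grp)
  out <- cohort[keep, , drop = FALSE]
  out$group <- factor(grp[keep], levels = intersect(levels_order,
                                                    unique(grp[keep])))
  sizes <- table(out$group)
  if (any(sizes < min_group)) {
    warning("group(s) below the size floor of ", min_group, ": ",
            paste(names(sizes)[sizes < min_group], collapse = ", "))
  }
  attr(out, "group_sizes") <- sizes
  attr(out, "n_excluded") <- sum(!keep)
  out
}
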