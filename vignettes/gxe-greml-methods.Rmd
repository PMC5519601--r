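---
title: "Estimating genome-wide genotype-by-environment interaction with multivariate GREML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genome-wide genotype-by-environment interaction with multivariate GREML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxegreml)
```

## The model

Consider a quantitative trait measured on unrelated individuals who fall
into $K$ discrete environment groups (the motivating design crosses two
binary early-life exposures -- breastfeeding and maternal smoking around
birth -- into four groups).  No individual is observed in more than one
environment, so the trait in each group is treated as a separate response
vector:

$$\mathbf{y}_i = \mathbf{X}_i \mathbf{b}_i + \mathbf{Z}_i \mathbf{g}_i +
\mathbf{e}_i, \qquad i = 1, \dots, K,$$

with fixed effects $\mathbf{b}_i$ (an intercept per group here; covariate
adjustment happens upstream), additive genetic values $\mathbf{g}_i$ and
residuals $\mathbf{e}_i$, both Gaussian with mean zero.  Genetic values of
different individuals are linked through the genomic relationship matrix
$\mathbf{A}$ built from genome-wide SNPs, so the phenotypic covariance of
the stacked data has blocks

$$\mathrm{block}_{ij}(\mathbf{V}) =
\mathbf{Z}_i \mathbf{A} \sigma_{g_{ij}} \mathbf{Z}_j' +
\delta_{ij}\, \mathbf{I}\sigma^2_{e_i},$$

where $\sigma^2_{g_i} = \sigma_{g_{ii}}$ is the genetic variance in
environment $i$ and $\sigma_{g_{ij}}$ the genetic covariance between
environments.  Residual covariances are structurally zero in this
genotype-by-environment (G$\times$E) layout because there are no repeated
measures.  When the blocks are different *traits* on overlapping
individuals instead, the residual covariance $\sigma_{e_{ij}}$ must be
modelled on shared individuals -- omitting it inflates the genetic
covariance -- and `greml(..., mode = "multi_trait")` does exactly that.

The quantity of interest is the cross-environment genetic correlation

$$r_G(i, j) = \frac{\sigma_{g_{ij}}}
{\sqrt{\sigma^2_{g_i}\sigma^2_{g_j}}},$$

which equals 1 when the same genetic effects operate in both environments.
A Wald test of $r_G = 1$, with the sampling variance of the ratio obtained
by the first-order delta method from the inverse information matrix, is
the package's test for genome-wide G$\times$E.  Correlations are
parameterized through unconstrained covariances, so estimates above 1
(which occur in practice when a group is small) are representable.

## Estimation

`greml_fit()` maximizes the restricted likelihood by average-information
(AI) REML.  Starting values are $\sigma^2_g = \sigma^2_e =
\mathrm{var}(y_i)/2$ per block (covariances start at half the geometric
mean of the corresponding variances).  The first update is an
expectation-maximization step, which is slow but safe far from the
optimum; subsequent updates solve the AI system, with step-halving
whenever a proposed step would decrease the restricted likelihood and a
floor of $10^{-6}\,\mathrm{var}(y_i)$ on every variance.  Accepted steps
therefore never decrease the likelihood.  Convergence is declared when
the change in log-likelihood falls below `tol` ($10^{-6}$ by default).

Numerical choices worth knowing:

* **Information matrix.**  Standard errors use the AI matrix at
  convergence by default (`info_type = "average"`); the observed
  information is available as an option.  When the information matrix is
  singular -- e.g. with an identity-like relationship matrix, where
  genetic and residual variances are not separately identifiable -- the
  fit is flagged `identifiable = FALSE` and every standard error is `NA`
  rather than a spurious number.
* **Boundary.**  A variance pinned at its floor sets a `boundary` flag;
  genetic correlations involving that block are refused instead of being
  reported with a meaningless standard error.
* **Non-convergence** raises a condition of class
  `"greml_convergence_error"` carrying the full likelihood trail.
* **Degenerate inputs.**  Duplicate sample IDs are rejected in G$\times$E
  mode (an individual cannot be in two environments); blocks need more
  observations than fixed-effect columns.

The engine is validated in the test suite against an independent direct
maximization of the explicit restricted likelihood (Nelder-Mead on
`determinant()`/`solve()` arithmetic) on small instances, agreeing to
$|\Delta \log L| < 10^{-6}$.

## The synthetic cohort generator

Real biobank genotypes and exposures cannot be redistributed, so
`simulate_genotypes()` and `simulate_gxe_cohort()` provide a fully
synthetic stand-in with *known* architecture:

* Genotypes are biallelic SNPs in linkage equilibrium under
  Hardy-Weinberg proportions, with allele frequencies uniform on a
  configurable range (default 0.05--0.5).  Linkage disequilibrium, real
  minor-allele-frequency spectra and imputation uncertainty are
  deliberately absent: the variance-component identities under test do
  not depend on them, but this also means passing tests say nothing about
  LD-induced biases in real data.
* The architecture is infinitesimal: every SNP is causal with Gaussian
  effects.  Cross-environment correlation is induced at the SNP-effect
  level -- independent effect vectors mixed through the Cholesky factor of
  the target correlation matrix -- because groups contain disjoint
  individuals, exactly as in the motivating design.
* Covariate confounding is linear and additive; the default set emulates
  sex, a year-of-birth-like continuous confounder and a genotyping-batch
  factor, with modest effects (0.05--0.1 phenotypic SD).  A monotone
  skewing option exercises the rank-based inverse normal transform.
* `apply_selection()` distorts a cohort by interval truncation, either on
  the phenotype itself or on a correlated environmental variable, to
  exercise the selection theory below.

Defaults used by the shipped end-to-end driver (`scripts/acceptance.R`):
four groups at 1/10-scale sizes of a large cognitive-trait cohort
(1320/531/436/257), per-group heritabilities 0.22/0.26/0.37/0.14 spanning
the range reported for such traits, a genetic correlation of 0.6 between
the first and third environments (a true interaction) and 0.8 elsewhere,
and 1000 SNPs.  Problem sizes throughout the tests (hundreds to a few
thousand individuals, hundreds to two thousand SNPs) were chosen so that
parameter-recovery and calibration claims can be demonstrated at desk
scale; they are far below biobank scale, where the same algebra applies
but dense $O(N^3)$ solves would not.

## Phenotype preparation and quality control

`adjust_phenotype()` regresses the raw trait on covariates by OLS and
returns residuals (listwise deletion of missing rows, aliased columns
dropped with a warning).  `inverse_normal_transform()` maps ranks to
normal quantiles with the Blom offset $3/8$ -- the most common choice in
genetic epidemiology; ties get average ranks.  Adjustment and
transformation are done once on the full sample before stratification;
standardizing within groups instead would not change the estimated
genetic correlations, since $r_G$ is scale-invariant per group.

`qc_filter()` applies the usual variant filters (MAF $> 0.01$,
Hardy-Weinberg $p \ge 10^{-4}$ by a 1-df chi-square without continuity
correction, variant missingness $\le 0.05$) before sample missingness
($\le 0.05$), in that fixed order.  `compute_grm()` uses the
allele-frequency-standardized estimator with mean imputation of missing
dosages to $2p$ and per-pair counts of informative variants;
`prune_related()` greedily removes the most-connected individual among
pairs with relationship $> 0.05$ (ties broken by sample-ID order), on the
full sample before stratification.

## Truncated-selection theory

Stratifying by an exposure correlated with the phenotype is a form of
selection, so one must ask whether it *creates* spurious G$\times$E.  For
a standard-normal trait $y = g + e$ with $h^2 = \mathrm{var}(g)$,
retaining the interval $t_1 < s < t_2$ of a selection variable $s$ with
$\mathrm{cor}(y, s) = r$ gives closed-form post-selection moments
(`post_selection_moments()`, `correlated_selection_moments()`), built
from the upper-tail proportions $K_j$ and selection intensities
$i_j = \phi(t_j)/K_j$.  Two facts matter:

1. The selected genetic values satisfy $g_s = c + b g$ with
   $b = \sqrt{1 - h^2 r^2 (1 - \mathrm{var}(y_s; r{=}1))} \le 1$: genetic
   variance shrinks, but the genetic *correlation* between two selected
   groups is exactly the unselected one
   ($b_1 b_2$ cancels in the correlation), whatever the truncation
   regimes.  `rg_under_selection()` returns this identity, and a
   full-pipeline simulation in the test suite confirms the estimator is
   unbiased under selection.
2. The phenotypic variance shrinks *more* than the genetic variance,
   because truncation induces a negative genetic-residual correlation in
   the survivors.  The post-selection variance ratio
   $h^2_s = \mathrm{var}(g_s)/\mathrm{var}(y_s)$ therefore exceeds $h^2$
   and can exceed 1; it is a variance ratio, not a squared correlation,
   once selection has broken the independence of $g$ and $e$.

Two derivations of the correlated-variable case are possible.  Under the
bivariate-normal model actually simulated ($s = r y + \sqrt{1 - r^2}\,
\varepsilon$), the selected genetic mean is $E(g_s) = h^2 E(y_s) \ne 0$
and $\mathrm{var}(g_s)$ carries the corresponding $-E(g_s)^2$ term.  An
alternative derivation argues $E(g_s) = 0$ (no genetic basis for the
environmental variable) while keeping the correlated second moment, and
so drops that term.  This package returns the exact moments -- they reduce
to the direct-selection case at $r = 1$ and match a $10^6$-draw
Monte-Carlo oracle -- and exposes the zero-mean variant as
`*_printed` fields; the two coincide for truncation intervals symmetric
about zero, and the $r_G$-invariance conclusion is identical either way.
The verbal description of "selecting below $t_1$ and above $t_2$"
(two-tail selection) is superseded by the algebra, whose denominators
$K_2 - K_1$ identify the selected set as the *interval* $t_1 < s < t_2$;
the simulator exposes the truncation region explicitly.

## Inference design

* **Pairwise contrasts.**  `gxe_scan()` performs one joint $K$-variate
  fit (more efficient and more powerful than separate bivariate fits) and
  reports all $K(K-1)/2$ correlations with Wald tests against 1, plus
  per-group $h^2$ with tests against 0.  The reported Bonferroni
  threshold divides $\alpha$ by traits $\times$ contrasts (0.05/24 = 0.002
  for four traits and four groups).
* **Permutation test.**  The tested null is $r_G = 1$, so the permutation
  statistic is $|\hat r_G - 1|$.  Environmental labels are shuffled
  jointly across the *union of the two contrasted groups only*,
  preserving the original group sizes; the empirical p-value uses the
  add-one estimator.  Shuffling across all four groups would test a
  different (global) null; the pairwise choice matches the pairwise Wald
  test it accompanies.  Non-convergent permutation replicates are redrawn
  up to a retry cap, then counted as failures; more than 20% failures
  aborts the test.
* **Sex stratification.**  `sex_stratified_scan()` doubles the groups by
  sex (an eight-variate fit for the four-way cross) and flags the
  within-environment male-female contrasts, which probe genotype-by-sex
  rather than genotype-by-environment interaction.
* **Functional partitioning.**  With several GRMs built from SNP
  categories, `partition_ratio()` reports the share of genetic variance
  (or covariance) attributable to one category, its delta-method SE, and
  a one-sided enrichment test against the category's SNP fraction.

## Genomic prediction and association

`gblup_predict()` implements GBLUP in GRM form (provably identical to
ridge-regression BLUP on standardized SNPs with $\lambda = M(1-h^2)/h^2$;
the identity is asserted to $10^{-8}$ in the tests).  The shrinkage $h^2$
is typically re-estimated in the discovery set; a fixed value can be
supplied.  Under a true cross-environment genetic correlation below 1,
discovery samples from the target's own environment predict better than
equally sized discovery samples from another environment -- the package's
simulated check of the consequence of G$\times$E for precision-medicine
style prediction.  `gwas_scan()` is a per-SNP least-squares scan on the
adjusted phenotype (no in-scan covariates, matching the residual-phenotype
workflow), with genomic-control $\lambda$ as the calibration summary.

## Known limitations

* Dense linear algebra limits fits to a few thousand observations per
  analysis; no sparse, low-rank or multi-threaded paths are provided.
* The simulator's linkage-equilibrium genotypes cannot expose biases that
  arise from LD between causal and tagging variants, assortative mating,
  or population structure; principal components are accepted as covariate
  columns but never computed here.
* Only additive genetic effects are modelled -- no dominance, epistasis or
  haplotype effects.
* The permutation and Wald tests assume a converged joint fit; with very
  small groups (tens of individuals) variance estimates hit the floor and
  contrasts are refused rather than reported.
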