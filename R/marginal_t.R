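#' Residual variance of a single-SNP regression from summary statistics
#'
#' Recovers the residual error variance of the per-SNP linear model from the
#' reported standard error, the minor allele frequency, and the sample size,
#' assuming covariates are independent of genotype:
#' `s2 = se^2 * 2 * n * maf * (1 - maf)`.
#'
#' @param se Standard error of the effect estimate (> 0).
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param n Study sample size (> 0).
#' @return Residual variance estimate(s), always positive.
#' @seealso [maf_weight()], which satisfies
#'   `error_variance(se, maf, n) * maf_weight(maf, n) == se^2`.
#' @export
error_variance <- function(se, maf, n) {
  if (any(!is.finite(se) | se <= 0)) stop("`se` must be positive and finite")
  .stopifnot_prob(maf, "maf", open0 = TRUE, open1 = FALSE)
  if (any(maf > 0.5)) stop("`maf` must not exceed 0.5 (fold to the minor allele)")
  if (any(!is.finite(n) | n <= 0)) stop("`n` must be positive")
  se^2 * 2 * n * maf * (1 - maf)
}

#' Per-SNP precision weight from allele frequency and sample size
#'
#' The weight `w = 1 / (2 * n * maf * (1 - maf))` relating the residual
#' variance to the sampling variance of the effect estimate:
#' `se^2 = s2 * w`.
#'
#' @inheritParams error_variance
#' @return Positive weight(s).
#' @export
maf_weight <- function(maf, n) {
  .stopifnot_prob(maf, "maf", open0 = TRUE, open1 = FALSE)
  if (any(maf > 0.5)) stop("`maf` must not exceed 0.5 (fold to the minor allele)")
  if (any(!is.finite(n) | n <= 0)) stop("`n` must be positive")
  1 / (2 * n * maf * (1 - maf))
}

#' Fit the scaled inverse-chi-squared prior on residual variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' of the variance prior by moment matching on the log variances
#' (digamma/trigamma equations), as implemented in [limma::fitFDist()].
#' `d0` may be `Inf` when the observed variances show no excess dispersion
#' over the chi-squared sampling noise.
#'
#' @param s_sq Vector of residual variance estimates (all > 0).
#' @param d1 Residual degrees of freedom of each variance estimate
#'   (a scalar, typically `n - 2` for single-SNP regressions).
#' @return List with elements `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s_sq, d1) {
  if (any(!is.finite(s_sq) | s_sq <= 0)) stop("all variances must be positive and finite")
  if (length(d1) != 1L || !is.finite(d1) || d1 <= 0) stop("`d1` must be a positive scalar")
  if (length(s_sq) < 2L || stats::var(log(s_sq)) == 0) {
    return(list(d0 = Inf, s0_sq = s_sq[[1L]]))
  }
  if (length(s_sq) < 100L) {
    warning("fewer than 100 variances; hyperparameter estimates may be unstable")
  }
  f <- limma::fitFDist(s_sq, df1 = d1)
  d0 <- f$df2
  if (!is.finite(d0) || d0 > 1e7) d0 <- Inf
  list(d0 = d0, s0_sq = f$scale)
}

#' Moderated t-statistics with empirical-Bayes variance shrinkage
#'
#' Replaces each SNP's residual variance by the posterior variance
#' `s2_post = (d0 * s0_sq + d1 * s2) / (d0 + d1)` and computes
#' `t = beta / sqrt(s2_post * w)`.  With `d0 = 0` this is the classical
#' t-statistic; with `d0 = Inf` every SNP uses the common prior variance.
#'
#' @param beta Effect size estimates.
#' @param s_sq Residual variances (see [error_variance()]).
#' @param w Per-SNP weights (see [maf_weight()]).
#' @param d0,s0_sq Variance prior hyperparameters from [fit_variance_prior()].
#' @param d1 Residual degrees of freedom.
#' @return Vector of moderated t-statistics.
#' @export
moderated_t <- function(beta, s_sq, w, d0, s0_sq, d1) {
  if (any(w <= 0)) stop("weights must be positive")
  s2_post <- if (is.infinite(d0)) {
    rep_len(s0_sq, length(s_sq))
  } else {
    (d0 * s0_sq + d1 * s_sq) / (d0 + d1)
  }
  beta / sqrt(s2_post * w)
}

#' Estimate the effect-size prior variance from the largest statistics
#'
#' Estimates `v0`, the variance hyperparameter of the normal prior on
#' non-zero standardized effect sizes, from the `ceiling(theta1 * m)` largest
#' absolute moderated t-statistics.  For the statistic of rank `r`, its
#' expected two-sided tail probability under the null/alternative mixture is
#' `(r - 0.5) / m`; solving the mixture tail for the alternative quantile
#' yields an implied scaling `v^2 = (t / q_target)^2` and an implied
#' `v0 = w * (v^2 - 1)`, clipped at zero and averaged over the target set.
#' Under the alternative the statistic is modeled as `v` times a null t
#' variate with `v = sqrt(1 + v0 / w)`, so `v0 = 0` recovers the null.
#'
#' @param t_mod Moderated t-statistics for all SNPs in the study.
#' @param d_total Total degrees of freedom `d0 + d1` (may be `Inf`).
#' @param w Per-SNP weights, recycled to `length(t_mod)`.
#' @param theta1 Marginal proportion of non-null SNPs in the study, in (0,1).
#' @return Non-negative scalar `v0`.
#' @seealso [scaling_factors()] for the per-SNP alternative scalings.
#' @export
estimate_v0 <- function(t_mod, d_total, w, theta1) {
  .stopifnot_prob(theta1, "theta1")
  m <- length(t_mod)
  w <- rep_len(w, m)
  ntarget <- ceiling(theta1 * m)
  if (ntarget < 1L) {
    warning("theta1 * m < 1; using the single largest statistic")
    ntarget <- 1L
  }
  o <- order(abs(t_mod), decreasing = TRUE)[seq_len(ntarget)]
  tt <- abs(t_mod[o])
  wt <- w[o]
  p0 <- 2 * stats::pt(-tt, df = d_total)
  ptarget <- ((seq_len(ntarget) - 0.5) / m - (1 - theta1) * p0) / theta1
  # quantile inversion is ill-conditioned once the implied alternative tail
  # probability approaches 1 (the target quantile collapses toward zero and
  # any statistic implies an enormous scaling); keep the well-conditioned
  # upper-tail terms, each of which is individually consistent for v0
  use <- ptarget > p0 & ptarget < 0.5
  if (!any(use)) return(0)
  qtarget <- stats::qt(ptarget[use] / 2, df = d_total, lower.tail = FALSE)
  v0 <- wt[use] * ((tt[use] / qtarget)^2 - 1)
  mean(pmax(v0, 0))
}

#' Per-SNP alternative scaling factors
#'
#' `v = sqrt(1 + v0 / w)`, the standard-deviation inflation of the
#' alternative t-distribution relative to the null; always >= 1.
#'
#' @param v0 Effect-size prior variance (>= 0).
#' @param w Per-SNP weights (> 0).
#' @return Vector of scaling factors.
#' @export
scaling_factors <- function(v0, w) {
  if (v0 < 0) stop("`v0` must be non-negative")
  if (any(w <= 0)) stop("weights must be positive")
  sqrt(1 + v0 / w)
}

#' Null and alternative marginal t densities
#'
#' The null density is the t density with `df` degrees of freedom; the
#' alternative is the scale family `f1(t) = dt(t / v, df) / v` with the
#' per-SNP scaling factor `v >= 1`.
#'
#' @param t Statistics at which to evaluate the densities.
#' @param df Degrees of freedom (may be `Inf` for the normal limit).
#' @param v Scaling factor(s), recycled against `t`.
#' @param log Return log densities?
#' @return List with components `f0` and `f1`.
#' @export
marginal_densities_t <- function(t, df, v, log = FALSE) {
  if (any(v < 1)) stop("scaling factors must be >= 1")
  f0 <- stats::dt(t, df = df, log = log)
  f1 <- if (log) {
    stats::dt(t / v, df = df, log = TRUE) - base::log(v)
  } else {
    stats::dt(t / v, df = df) / v
  }
  list(f0 = f0, f1 = f1)
}

#' Fit the per-study t-mode marginal model
#'
#' Bundles the degrees of freedom, the estimated `v0` and the per-SNP
#' scaling factors into the marginal model object used when assembling
#' pattern-specific joint densities.
#'
#' @param t_mod Moderated t-statistics (or z-scores) for the study.
#' @param df Total degrees of freedom (may be `Inf`).
#' @param w Per-SNP weights (default 1, i.e. unit-variance statistics).
#' @param theta1 Marginal non-null proportion for the study.
#' @return Object of class `patmix_marg_t` with fields `df`, `v0`, `v`,
#'   `w`, `theta1` and the null standard deviation `sd0` of the normal
#'   approximation.
#' @export
fit_marginal_t <- function(t_mod, df, w = 1, theta1) {
  if (df <= 2) stop("total degrees of freedom must exceed 2")
  w <- rep_len(w, length(t_mod))
  v0 <- estimate_v0(t_mod, df, w, theta1)
  structure(
    list(mode = "t", df = df, v0 = v0, v = scaling_factors(v0, w),
         w = w, theta1 = theta1, sd0 = sqrt(.t_var_ratio(df))),
    class = "patmix_marg_t"
  )
}

# full t-mode preprocessing from raw summary statistics
#' Moderate a study's summary statistics
#'
#' Convenience wrapper running the full per-study t-mode preprocessing:
#' residual variances from MAF, variance-prior fit, moderated t-statistics,
#' and per-SNP weights.
#'
#' @param beta,se Effect sizes and standard errors.
#' @param maf Minor allele frequencies in (0, 0.5].
#' @param n Study sample size.
#' @param df Residual degrees of freedom `d1` (default `n - 2`).
#' @return List with `t_mod`, `w`, `d_total`, `d0`, `s0_sq`, `s_sq`.
#' @export
moderate_tstats <- function(beta, se, maf, n, df = n - 2) {
  s_sq <- error_variance(se, maf, n)
  w <- maf_weight(maf, n)
  prior <- fit_variance_prior(s_sq, df)
  t_mod <- moderated_t(beta, s_sq, w, prior$d0, prior$s0_sq, df)
  d_total <- prior$d0 + df
  if (d_total <= 2) stop("moderated degrees of freedom must exceed 2")
  list(t_mod = t_mod, w = w, d_total = d_total,
       d0 = prior$d0, s0_sq = prior$s0_sq, s_sq = s_sq)
}
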