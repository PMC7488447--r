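#' Fit the joint association pattern mixture model
#'
#' `patmix()` is the main entry point.  It takes an m x J matrix of
#' association summary statistics for m SNPs across J studies and fits an
#' empirical-Bayes mixture over all K = 2^J joint association patterns:
#'
#' 1. per-study empirical null and alternative marginal densities are
#'    estimated — from moderated t-statistics (`mode = "t"`) or from
#'    `-2 log(p)` statistics with a scaled chi-squared tail fit
#'    (`mode = "p"`);
#' 2. the inter-study null correlation induced by sample overlap is
#'    estimated from SNPs that look null in every study (unless
#'    `independent = TRUE`);
#' 3. pattern-specific joint log densities are assembled and held fixed;
#' 4. the pattern proportions `pi` are estimated by EM and per-SNP
#'    posterior pattern probabilities are computed.
#'
#' @param x m x J numeric matrix.  In t-mode, moderated t-statistics (or
#'   z-scores); use [moderate_tstats()] or [patmix_tables()] to produce them
#'   from effect sizes and standard errors.  In P-mode, two-sided P values
#'   in (0, 1].
#' @param theta1 Per-study marginal non-null proportions (length J, or a
#'   scalar recycled).  Typical values: 1e-3 for omics QTL studies, 1e-5
#'   for GWAS.
#' @param mode `"t"` or `"p"`.
#' @param df Per-study total degrees of freedom (t-mode; may be `Inf`).
#' @param weights m x J matrix (or scalar) of per-SNP weights `w_ij`
#'   (t-mode; default 1 for unit-variance statistics).
#' @param independent Treat studies as independent (product densities)
#'   rather than coupling them through the estimated null correlation.
#' @param gamma Optional known null correlation matrix; estimated from the
#'   data when `NULL`.
#' @param null_threshold `|t|` cut defining null-like SNPs for the
#'   correlation estimate (default 5).
#' @param tol,max_iter EM convergence controls.
#' @param keep_densities Keep the m x K log-density matrix on the object?
#' @param snp_id Optional SNP identifiers (length m).
#' @return An object of class `"patmix"` with components `pi` (pattern
#'   proportions), `post` (m x K posterior matrix), `a_hat` (most probable
#'   pattern per SNP), `Q`, `Gamma`, `marginals`, `loglik`, and the inputs
#'   needed by [conditional_posterior()].  Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`, `simulate`.
#' @seealso [collapse_posterior()], [estimated_fdr()],
#'   [conditional_posterior()], [simulate_stats_direct()]
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_stats_direct(scenario_spec(
#'   J = 2, m = 5000, n = 1000,
#'   pi_true = c(0.99, 0.004, 0.004, 0.002), effect_sd = 0.2))
#' fit <- patmix(sim$T, theta1 = 0.006, df = 998)
#' coef(fit)
patmix <- function(x, theta1, mode = c("t", "p"), df = NULL, weights = NULL,
                   independent = FALSE, gamma = NULL, null_threshold = 5,
                   tol = 1e-6, max_iter = 1000L, keep_densities = FALSE,
                   snp_id = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  m <- nrow(x); J <- ncol(x)
  if (J < 1L) stop("`x` needs at least one study column")
  theta1 <- rep_len(theta1, J)
  .stopifnot_prob(theta1, "theta1")
  Q <- make_patterns(J)
  K <- nrow(Q)

  if (mode == "t") {
    if (is.null(df)) stop("t-mode requires per-study degrees of freedom `df`")
    df <- rep_len(df, J)
    if (is.null(weights)) weights <- matrix(1, m, J)
    if (!is.matrix(weights)) weights <- matrix(weights, m, J)
    T_stat <- x
    marginals <- lapply(seq_len(J), function(j) {
      fit_marginal_t(T_stat[, j], df[j], weights[, j], theta1[j])
    })
  } else {
    T_stat <- apply(x, 2L, p_to_stat)
    marginals <- lapply(seq_len(J), function(j) {
      fit_marginal_p(x[, j], theta1[j])
    })
  }

  Gamma <- NULL
  if (!independent) {
    if (!is.null(gamma)) {
      stopifnot(.is_square(gamma), nrow(gamma) == J)
      Gamma <- .project_psd_corr(gamma)
    } else if (J == 1L) {
      Gamma <- matrix(1, 1L, 1L)
    } else if (mode == "t") {
      Gamma <- estimate_null_correlation(T_stat, threshold = null_threshold)
    } else {
      # correlation of null normal scores of the chi-squared statistics
      Z0 <- apply(T_stat, 2L, .chisq_normal_scores, df = 2)
      Gamma <- estimate_null_correlation(Z0, threshold = null_threshold)
    }
  }

  logD <- pattern_log_densities(T_stat, marginals, Q, Gamma,
                                independent = independent)
  # independence initialization: product of per-study marginal proportions
  init <- apply(Q, 1L, function(qk) prod(ifelse(qk == 1L, theta1, 1 - theta1)))
  init <- init / sum(init)
  em <- em_estimate_pi(logD, init = init, tol = tol, max_iter = max_iter)
  pp <- posterior_probabilities(logD, em$pi)

  structure(
    list(call = match.call(), mode = mode, m = m, J = J, K = K,
         Q = Q, labels = pattern_labels(Q), theta1 = theta1, df = df,
         marginals = marginals, Gamma = Gamma, independent = independent,
         pi = stats::setNames(em$pi, pattern_labels(Q)),
         post = pp$post, a_hat = pp$a_hat,
         loglik = em$loglik, niter = em$niter, converged = em$converged,
         T = T_stat, snp_id = snp_id,
         logD = if (keep_densities) logD else NULL),
    class = "patmix"
  )
}

#' @export
print.patmix <- function(x, ...) {
  cat(sprintf("Joint association pattern mixture (%s-mode)\n",
              if (x$mode == "t") "t-statistic" else "P-value"))
  cat(sprintf("  %d SNPs x %d studies; %d patterns; EM %sconverged in %d iterations\n",
              x$m, x$J, x$K, if (x$converged) "" else "NOT ", x$niter))
  nz <- x$pi[x$pi > 1 / (50 * x$m)]
  cat("  estimated pattern proportions (%):\n")
  print(round(100 * sort(nz, decreasing = TRUE), 4))
  invisible(x)
}

#' @export
coef.patmix <- function(object, ...) object$pi

#' @export
summary.patmix <- function(object, lambda = c(0.8, 0.9), ...) {
  calls <- table(factor(object$a_hat, levels = seq_len(object$K),
                        labels = object$labels))
  p_any <- 1 - object$post[, 1L]
  fdr <- vapply(lambda, function(l) {
    if (any(p_any >= l)) estimated_fdr(p_any, l) else NA_real_
  }, numeric(1))
  out <- list(pi = object$pi, calls = calls, Gamma = object$Gamma,
              lambda = lambda, est_fdr_any = stats::setNames(fdr, lambda),
              mode = object$mode, m = object$m, J = object$J,
              marginals = object$marginals)
  class(out) <- "summary.patmix"
  out
}

#' @export
print.summary.patmix <- function(x, ...) {
  cat(sprintf("%d SNPs x %d studies (%s-mode)\n\n", x$m, x$J, x$mode))
  cat("Pattern proportions (%) and most-probable-pattern counts:\n")
  print(data.frame(pi_pct = round(100 * x$pi, 4), n_assigned = as.integer(x$calls),
                   row.names = names(x$pi)))
  if (!is.null(x$Gamma) && nrow(x$Gamma) > 1L) {
    cat("\nEstimated null correlation (sample overlap):\n")
    print(round(x$Gamma, 3))
  }
  cat("\nEstimated FDR for 'associated with at least one trait':\n")
  print(round(x$est_fdr_any, 4))
  invisible(x)
}

#' Posterior pattern probabilities for new statistics
#'
#' Evaluates the fitted mixture on new rows of statistics, holding the
#' marginal densities, null correlation, and pattern proportions fixed.
#'
#' @param object A fitted [patmix()] model.
#' @param newdata Matrix of statistics with J columns (same scale as the
#'   training statistics: moderated t in t-mode, P values in P-mode).
#' @param weights Per-SNP weights for the new rows (t-mode; default 1).
#' @param ... Unused.
#' @return Matrix of posterior probabilities, one row per input row.
#' @export
predict.patmix <- function(object, newdata, weights = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$J) stop("`newdata` must have J columns")
  m2 <- nrow(newdata)
  if (object$mode == "t") {
    if (is.null(weights)) weights <- matrix(1, m2, object$J)
    if (!is.matrix(weights)) weights <- matrix(weights, m2, object$J)
    marg <- lapply(seq_len(object$J), function(j) {
      mg <- object$marginals[[j]]
      mg$w <- weights[, j]
      mg$v <- scaling_factors(mg$v0, mg$w)
      mg
    })
    T_new <- newdata
  } else {
    marg <- object$marginals
    T_new <- apply(newdata, 2L, p_to_stat)
  }
  logD <- pattern_log_densities(T_new, marg, object$Q, object$Gamma,
                                independent = object$independent)
  posterior_probabilities(logD, object$pi)$post
}

#' Plot fitted marginal null and alternative densities
#'
#' Overlays the fitted null and (scaled) alternative marginal densities of
#' one study on the histogram of its statistics — the t-mode densities on
#' the moderated-t scale, or the chi-squared-family densities on the
#' `-2 log(p)` scale.
#'
#' @param x A fitted [patmix()] model.
#' @param study Study index to display.
#' @param breaks Histogram breaks.
#' @param xlim Optional x range.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.patmix <- function(x, study = 1L, breaks = 100L, xlim = NULL, ...) {
  t <- x$T[, study]
  mg <- x$marginals[[study]]
  if (is.null(xlim)) xlim <- stats::quantile(t, c(0.001, 0.999))
  graphics::hist(t, breaks = breaks, freq = FALSE, xlim = xlim,
                 main = sprintf("Study %d marginal densities", study),
                 xlab = if (x$mode == "t") "moderated t" else "-2 log(p)", ...)
  grid_t <- seq(xlim[1L], xlim[2L], length.out = 400L)
  if (x$mode == "t") {
    vbar <- stats::median(mg$v)
    d <- marginal_densities_t(grid_t, mg$df, vbar)
  } else {
    d <- marginal_densities_p(pmax(grid_t, 1e-9), mg$A, mg$d_alt)
  }
  graphics::lines(grid_t, d$f0, col = "steelblue", lwd = 2)
  graphics::lines(grid_t, d$f1, col = "firebrick", lwd = 2, lty = 2)
  graphics::legend("topright", c("null", "alternative (typical scaling)"),
                   col = c("steelblue", "firebrick"), lty = c(1, 2), lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Simulate statistics from a fitted pattern mixture
#'
#' Draws SNP statistic vectors from the fitted mixture: patterns from the
#' estimated proportions, then statistics from the pattern's normal
#' approximation (t-mode, with the study coupling `Gamma`) or from the
#' fitted chi-squared marginals (P-mode, independently across studies).
#'
#' @param object A fitted [patmix()] model.
#' @param nsim Number of SNP rows to draw.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return List with `T` (nsim x J matrix) and `pattern` (true indices).
#' @export
simulate.patmix <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  J <- object$J
  a <- sample.int(object$K, nsim, replace = TRUE, prob = object$pi)
  T_out <- matrix(0, nsim, J)
  if (object$mode == "t") {
    G <- if (is.null(object$Gamma)) diag(J) else object$Gamma
    Z <- matrix(stats::rnorm(nsim * J), nsim, J) %*% chol(G)
    vbar <- vapply(object$marginals, function(mg) stats::median(mg$v), numeric(1))
    for (j in seq_len(J)) {
      mg <- object$marginals[[j]]
      sd_null <- mg$sd0
      sd_j <- ifelse(object$Q[a, j] == 1L, vbar[j] * sd_null, sd_null)
      T_out[, j] <- Z[, j] * sd_j
    }
  } else {
    for (j in seq_len(J)) {
      mg <- object$marginals[[j]]
      alt <- object$Q[a, j] == 1L
      T_out[!alt, j] <- stats::rchisq(sum(!alt), df = 2)
      T_out[alt, j] <- mg$A * stats::rchisq(sum(alt), df = mg$d_alt)
    }
  }
  list(T = T_out, pattern = a)
}
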