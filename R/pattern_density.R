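#' Estimate the inter-study null correlation from null-like statistics
#'
#' Sample overlap between studies correlates their test statistics even at
#' truly null SNPs.  Pooling SNPs whose statistics are modest in every study
#' (absolute value below `threshold` on the t/z scale) isolates that
#' sample-driven correlation from the biological co-occurrence of
#' associations, which is modeled separately by the mixing proportions.
#' The Pearson correlation of the pooled rows is projected to the positive
#' semidefinite cone (eigenvalue clipping) if truncation renders it
#' indefinite.
#'
#' @param T m x J matrix of association statistics.
#' @param threshold Null-likeness cut on `|t|` (default 5).
#' @param min_rows Minimum number of null-like SNPs required (default 1000).
#' @return J x J correlation matrix with unit diagonal.
#' @export
estimate_null_correlation <- function(T, threshold = 5, min_rows = 1000L) {
  T <- as.matrix(T)
  J <- ncol(T)
  if (J == 1L) return(matrix(1, 1L, 1L))
  keep <- rowSums(abs(T) < threshold) == J
  if (sum(keep) < min_rows) {
    stop(sprintf(
      "only %d SNPs look null in all %d studies (|t| < %g); increase the threshold",
      sum(keep), J, threshold))
  }
  .project_psd_corr(stats::cor(T[keep, , drop = FALSE]))
}

# per-SNP standard deviations of the normal approximation under one pattern:
# sd_ij = v_ij^{q_kj} * sqrt(d_j / (d_j - 2)); q = 0 gives the null sd
.pattern_sds <- function(marginals, qk, m) {
  J <- length(marginals)
  S <- matrix(0, m, J)
  for (j in seq_len(J)) {
    mg <- marginals[[j]]
    S[, j] <- if (qk[j] == 1L) mg$v * mg$sd0 else mg$sd0
  }
  S
}

# map -2 log p statistics to normal scores under a chi-squared-family cdf,
# working on the log tail for numerical stability
.chisq_normal_scores <- function(t, df, A = 1) {
  lp <- stats::pchisq(t / A, df = df, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  pmin(pmax(z, -38), 38)
}

#' Pattern-specific joint log densities
#'
#' Computes the m x K matrix of log joint densities of each SNP's statistic
#' vector under each association pattern.
#'
#' With `independent = TRUE` the joint density of pattern k is the product
#' of the per-study marginal null/alternative densities selected by the
#' pattern (t densities in t-mode, chi-squared densities in P-mode).
#'
#' With `independent = FALSE` (the default when samples may overlap) the
#' t-mode marginals are approximated by zero-mean normals with variances
#' `v^(2q) * d/(d-2)` and coupled through the null correlation `Gamma`:
#' pattern k's density is multivariate normal with covariance
#' `S^(1/2) Gamma S^(1/2)` where `S` is the diagonal matrix of
#' pattern-specific variances.  In P-mode the chi-squared marginals are
#' coupled by a Gaussian copula with correlation `Gamma` (a documented
#' approximation; the marginal densities are exact).
#'
#' @param T m x J statistic matrix (moderated t or -2 log p).
#' @param marginals List of J fitted marginal models
#'   ([fit_marginal_t()] / [fit_marginal_p()]).
#' @param Q Pattern matrix from [make_patterns()].
#' @param Gamma Null correlation matrix (required unless `independent`).
#' @param independent Treat the studies as independent?
#' @return m x K matrix of finite log densities; columns named by pattern.
#' @export
pattern_log_densities <- function(T, marginals, Q, Gamma = NULL,
                                  independent = FALSE) {
  T <- as.matrix(T)
  m <- nrow(T); J <- ncol(T); K <- nrow(Q)
  stopifnot(length(marginals) == J, ncol(Q) == J)
  mode <- marginals[[1L]]$mode
  logD <- matrix(0, m, K, dimnames = list(NULL, pattern_labels(Q)))

  if (independent) {
    lf0 <- matrix(0, m, J); lf1 <- matrix(0, m, J)
    for (j in seq_len(J)) {
      mg <- marginals[[j]]
      d <- if (mode == "t") {
        marginal_densities_t(T[, j], mg$df, mg$v, log = TRUE)
      } else {
        marginal_densities_p(T[, j], mg$A, mg$d_alt, log = TRUE)
      }
      lf0[, j] <- d$f0; lf1[, j] <- d$f1
    }
    for (k in seq_len(K)) {
      qk <- Q[k, ]
      logD[, k] <- lf0 %*% (1 - qk) + lf1 %*% qk
    }
    if (!all(is.finite(logD))) stop("non-finite pattern log densities")
    return(logD)
  }

  if (is.null(Gamma)) stop("`Gamma` is required unless `independent = TRUE`")
  stopifnot(.is_square(Gamma), nrow(Gamma) == J)
  Gi <- solve(Gamma)
  ldet <- as.numeric(determinant(Gamma, logarithm = TRUE)$modulus)

  if (mode == "t") {
    for (k in seq_len(K)) {
      S <- .pattern_sds(marginals, Q[k, ], m)
      Z <- T / S
      quad <- rowSums((Z %*% Gi) * Z)
      logD[, k] <- -J / 2 * log(2 * pi) - 0.5 * ldet -
        rowSums(log(S)) - 0.5 * quad
    }
  } else {
    # Gaussian copula over the exact chi-squared-family marginals
    for (k in seq_len(K)) {
      qk <- Q[k, ]
      lmarg <- matrix(0, m, J); Z <- matrix(0, m, J)
      for (j in seq_len(J)) {
        mg <- marginals[[j]]
        if (qk[j] == 1L) {
          lmarg[, j] <- stats::dchisq(T[, j] / mg$A, df = mg$d_alt, log = TRUE) -
            log(mg$A)
          Z[, j] <- .chisq_normal_scores(T[, j], mg$d_alt, mg$A)
        } else {
          lmarg[, j] <- stats::dchisq(T[, j], df = 2, log = TRUE)
          Z[, j] <- .chisq_normal_scores(T[, j], 2)
        }
      }
      quad <- rowSums((Z %*% Gi) * Z)
      logD[, k] <- rowSums(lmarg) - 0.5 * ldet - 0.5 * (quad - rowSums(Z^2))
    }
  }
  if (!all(is.finite(logD))) stop("non-finite pattern log densities")
  logD
}

#' Pattern-specific variances of the normal approximation
#'
#' Returns the m x J matrix of variances `sigma^2 = v^(2q) * d/(d-2)` used
#' for pattern `k` of `Q` in the correlated-sample normal approximation.
#'
#' @inheritParams pattern_log_densities
#' @param k Pattern index.
#' @return m x J matrix of variances.
#' @export
pattern_variances <- function(marginals, Q, k, m = NULL) {
  if (is.null(m)) m <- length(marginals[[1L]]$v)
  .pattern_sds(marginals, Q[k, ], m)^2
}
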