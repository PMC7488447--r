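#' Estimate pattern proportions by EM
#'
#' Given the fixed pattern log densities, runs the EM algorithm for the
#' mixing proportions of the K-component mixture: the E-step computes
#' per-SNP posterior pattern probabilities under the current proportions,
#' the M-step averages each posterior column.  The densities are never
#' re-estimated.  A floor of `1/(100 m)` is kept on the working proportions
#' to prevent absorbing zeros with very sparse patterns; the returned
#' estimate is the final unfloored column mean.
#'
#' @param logD m x K matrix of pattern log densities.
#' @param init Initial proportions on the simplex (default uniform).
#' @param tol Convergence tolerance on `max |pi_new - pi_old|`.
#' @param max_iter Iteration cap.
#' @return List with `pi` (length-K proportions), `loglik` (observed-data
#'   log-likelihood per iteration, non-decreasing), `niter`, `converged`.
#' @export
em_estimate_pi <- function(logD, init = NULL, tol = 1e-6, max_iter = 1000L) {
  if (!all(is.finite(logD))) stop("`logD` must be finite")
  if (tol <= 0) stop("`tol` must be positive")
  m <- nrow(logD); K <- ncol(logD)
  if (is.null(init)) init <- rep(1 / K, K)
  if (length(init) != K || any(init < 0) || abs(sum(init) - 1) > 1e-8) {
    stop("`init` must be a length-K vector on the simplex")
  }
  floor_pi <- 1 / (100 * m)
  pi_work <- pmax(init, floor_pi)
  pi_work <- pi_work / sum(pi_work)
  loglik <- numeric(0)
  pi_raw <- pi_work
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- sweep(logD, 2L, log(pi_work), `+`)
    mx <- apply(A, 1L, max)
    P <- exp(A - mx)
    rs <- rowSums(P)
    loglik[it] <- sum(mx + log(rs))
    pi_raw <- colSums(P / rs) / m
    delta <- max(abs(pi_raw - pi_work))
    pi_new <- pmax(pi_raw, floor_pi)
    pi_new <- pi_new / sum(pi_new)
    pi_work <- pi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(pi = pi_raw / sum(pi_raw), loglik = loglik, niter = length(loglik),
       converged = converged)
}

#' Per-SNP posterior pattern probabilities
#'
#' The posterior probability that SNP i belongs to pattern k is
#' `pi_k D_k(T_i) / sum_b pi_b D_b(T_i)`, evaluated in log space with a
#' row-wise log-sum-exp so every row normalizes exactly.
#'
#' @param logD m x K pattern log densities.
#' @param pi Length-K mixing proportions on the simplex.
#' @return List with `post` (m x K row-stochastic matrix) and `a_hat`
#'   (per-SNP maximum-probability pattern index; exact ties resolve to the
#'   pattern with fewer associations, which comes first in canonical order).
#' @export
posterior_probabilities <- function(logD, pi) {
  K <- ncol(logD)
  if (length(pi) != K || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("`pi` must be a length-K vector on the simplex")
  }
  lp <- log(ifelse(pi > 0, pi, .Machine$double.xmin))
  A <- sweep(logD, 2L, lp, `+`)
  # guard true zeros: -Inf log-weight removes the component entirely
  A[, pi == 0] <- -Inf
  mx <- apply(A, 1L, max)
  P <- exp(A - mx)
  post <- P / rowSums(P)
  colnames(post) <- colnames(logD)
  list(post = post, a_hat = max.col(post, ties.method = "first"))
}

#' Collapse posterior probabilities over a pattern group
#'
#' Sums the per-SNP posterior probabilities over a set of mutually
#' exclusive patterns (e.g. "associated with the trait and at least one
#' omics trait").
#'
#' @param post m x K posterior matrix.
#' @param Q Pattern matrix matching the columns of `post`.
#' @param group Group specification accepted by [parse_pattern_group()].
#' @return Vector of collapsed probabilities in `[0, 1]`.
#' @export
collapse_posterior <- function(post, Q, group) {
  idx <- parse_pattern_group(Q, group)
  rowSums(post[, idx, drop = FALSE])
}

#' Posterior-probability-based estimated FDR
#'
#' For a probability threshold `lambda`, the estimated false discovery rate
#' among SNPs called at that threshold is
#' `sum_i (1 - P_i) 1(P_i >= lambda) / #\{P_i >= lambda\}`.
#'
#' @param p_hat Collapsed posterior probabilities for the pattern group of
#'   interest.
#' @param lambda Probability threshold in (0, 1).
#' @return The estimated FDR, or `NA` (with a warning) when no SNP exceeds
#'   the threshold — an empty discovery set has no defined FDR.
#' @export
estimated_fdr <- function(p_hat, lambda) {
  .stopifnot_prob(lambda, "lambda")
  keep <- p_hat >= lambda
  n <- sum(keep)
  if (n == 0L) {
    warning("no probabilities reach the threshold; estimated FDR is undefined")
    return(NA_real_)
  }
  sum(1 - p_hat[keep]) / n
}

#' Combine group-level null probabilities into an overall probability
#'
#' When studies are analyzed in independent groups, the probability that a
#' SNP is associated with at least one trait overall is one minus the
#' product of the per-group probabilities of no association.
#'
#' @param group_null_probs Per-group probabilities of no association, each
#'   in `[0, 1]`.
#' @return `1 - prod(group_null_probs)`, in `[0, 1]`.
#' @export
group_product <- function(group_null_probs) {
  .stopifnot_prob(group_null_probs, "group_null_probs",
                  open0 = FALSE, open1 = FALSE)
  1 - prod(group_null_probs)
}
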