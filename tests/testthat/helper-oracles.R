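# Independent brute-force oracles used across test files.  These
# deliberately avoid the package's vectorized code paths.

# dense per-row multivariate normal log density with covariance
# diag(sds) %*% Gamma %*% diag(sds), computed via solve()/determinant()
naive_mvn_logdens <- function(x, sds, Gamma, mean = rep(0, length(x))) {
  S <- diag(sds, nrow = length(sds)) %*% Gamma %*% diag(sds, nrow = length(sds))
  J <- length(x)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  z <- x - mean
  -J / 2 * log(2 * pi) - 0.5 * ld - 0.5 * as.numeric(t(z) %*% solve(S) %*% z)
}

# conditional density of element 1 given the rest, from the joint and the
# marginal of the conditioning block: f(x1 | x2) = f(x) / f(x2)
naive_conditional_logdens <- function(x, Sigma) {
  J <- length(x)
  ld_joint <- naive_mvn_logdens(x, rep(1, J), Sigma) # Sigma passed whole
  S22 <- Sigma[-1, -1, drop = FALSE]
  ld2 <- naive_mvn_logdens(x[-1], rep(1, J - 1), S22)
  ld_joint - ld2
}

# tiny deterministic t-mode fit used by several interface tests
small_fit <- function(m = 20000, seed = 42, J = 3, overlap = 0.2) {
  pi_true <- c(0.99, rep(0.01 / (2^J - 1), 2^J - 1))
  spec <- scenario_spec(J = J, m = m, n = 1000, overlap_corr = overlap,
                        pi_true = pi_true, effect_sd = 0.3, seed = seed)
  sim <- simulate_stats_direct(spec)
  fit <- patmix(sim$T, theta1 = 0.01, df = 998)
  list(fit = fit, sim = sim)
}
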