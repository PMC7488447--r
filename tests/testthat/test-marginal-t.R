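test_that("error variance and weight obey their closed forms and identity", {
  expect_equal(error_variance(se = 0.1, maf = 0.5, n = 200), 1.0)
  expect_equal(error_variance(se = 0.05, maf = 0.25, n = 1000), 0.9375)
  expect_equal(maf_weight(maf = 0.5, n = 200), 0.01)
  expect_equal(maf_weight(maf = 0.1, n = 500), 1 / 90)

  # se^2 = s^2 * w exactly, for random legal inputs
  set.seed(1)
  se <- runif(50, 0.01, 2); maf <- runif(50, 0.01, 0.5); n <- sample(50:5000, 50)
  expect_equal(error_variance(se, maf, n) * maf_weight(maf, n), se^2)

  expect_error(error_variance(0, 0.3, 100), "positive")
  expect_error(error_variance(0.1, 0.6, 100), "0.5")
  expect_error(maf_weight(0, 100), "0, 1")
})

test_that("variance prior fit recovers known hyperparameters and degenerates cleanly", {
  expect_equal(fit_variance_prior(rep(2.5, 200), 100),
               list(d0 = Inf, s0_sq = 2.5))

  # s^2 ~ s0^2 * (d0 / chisq_d0) * (chisq_d1 / d1): scaled-F draws with known truth
  set.seed(7)
  m <- 1e5; d0 <- 4; s0 <- 1; d1 <- 998
  s_sq <- s0 * (d0 / rchisq(m, d0)) * (rchisq(m, d1) / d1)
  fit <- fit_variance_prior(s_sq, d1)
  expect_lt(abs(fit$d0 - d0), 0.5)
  expect_lt(abs(fit$s0_sq - s0), 0.05)

  # doubling all variances doubles s0_sq and leaves d0 unchanged
  fit2 <- fit_variance_prior(2 * s_sq, d1)
  expect_equal(fit2$d0, fit$d0, tolerance = 1e-6)
  expect_equal(fit2$s0_sq, 2 * fit$s0_sq, tolerance = 1e-6)
})

test_that("moderated t interpolates between classical and fully shrunk", {
  set.seed(2)
  beta <- rnorm(100); s_sq <- rchisq(100, 10) / 10; w <- runif(100, 0.005, 0.02)
  # no shrinkage limit: d0 = 0 gives the classical t
  expect_equal(moderated_t(beta, s_sq, w, 0, 5, 100), beta / sqrt(s_sq * w))
  # full shrinkage: d0 = Inf uses s0_sq for every SNP
  expect_equal(moderated_t(beta, s_sq, w, Inf, 2, 100), beta / sqrt(2 * w))
  # closed form
  expect_equal(moderated_t(1, 1, 0.01, Inf, 1, 100), 10)
  # posterior variance lies between the prior and the observation
  s2p <- (4 * 1 + 100 * s_sq) / 104
  expect_true(all(s2p >= pmin(s_sq, 1) & s2p <= pmax(s_sq, 1)))
})

test_that("v0 estimation is near zero on pure-null data and recovers truth", {
  set.seed(3)
  m <- 1e6; df <- 998; theta <- 1e-3; w <- 0.01
  v0_true <- 0.04
  v <- sqrt(1 + v0_true / w)
  reps <- t(replicate(3, {
    t_null <- rt(m, df)
    v0_null <- estimate_v0(t_null, df, w = w, theta1 = theta)
    n_alt <- rbinom(1, m, theta)
    t_mix <- c(rt(m - n_alt, df), v * rt(n_alt, df))
    c(null = v0_null, mix = estimate_v0(t_mix, df, w, theta))
  }))
  # pure null: implied alternative scaling stays close to 1
  expect_true(all(sqrt(1 + reps[, "null"] / w) < 1.5))
  expect_lt(mean(reps[, "null"]), v0_true / 3)
  # planted alternatives: recovered within 20% relative error on average
  expect_lt(abs(mean(reps[, "mix"]) - v0_true) / v0_true, 0.2)

  # closed-form scaling factor
  expect_equal(scaling_factors(0.03, 0.01), 2)
})

test_that("v0 estimator agrees with the limma tmixture cross-check", {
  set.seed(4)
  m <- 2e5; df <- 500; theta <- 2e-3; w <- 0.01
  v <- sqrt(1 + 0.06 / w)
  n_alt <- rbinom(1, m, theta)
  t_mix <- sample(c(rt(m - n_alt, df), v * rt(n_alt, df)))
  ours <- estimate_v0(t_mix, df, w, theta)
  # limma targets the top proportion/2 statistics; same quantile-matching idea
  ref <- limma::tmixture.vector(t_mix, rep(sqrt(w), m), df, theta)
  expect_lt(abs(ours - ref) / ref, 0.5)
})

test_that("marginal t densities integrate, scale, and order their tails", {
  d <- marginal_densities_t(0.7, df = 10, v = 1)
  expect_equal(d$f1, d$f0)
  expect_equal(marginal_densities_t(0, 10, 3)$f1,
               marginal_densities_t(0, 10, 3)$f0 / 3)

  # f1 normalizes
  int <- integrate(function(t) marginal_densities_t(t, 8, 2.5)$f1,
                   -Inf, Inf, rel.tol = 1e-9)
  expect_lt(abs(int$value - 1), 1e-6)

  # heavier alternative tail: f1/f0 increasing in |t| for v > 1
  tt <- seq(0, 12, by = 0.25)
  r <- marginal_densities_t(tt, 30, 2)$f1 / marginal_densities_t(tt, 30, 2)$f0
  expect_true(all(diff(r) > 0))
})

test_that("full moderation pipeline reproduces the classical t when unshrunk", {
  set.seed(5)
  m <- 500; n <- 400
  maf <- runif(m, 0.05, 0.5)
  se <- runif(m, 0.02, 0.2)
  beta <- rnorm(m, 0, se)
  mod <- moderate_tstats(beta, se, maf, n)
  expect_equal(length(mod$t_mod), m)
  expect_true(all(is.finite(mod$t_mod)))
  expect_gt(mod$d_total, n - 2)
  # se^2 = s_sq * w carried through
  expect_equal(mod$s_sq * mod$w, se^2)
})
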