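# a small deterministic fit whose per-SNP scalings we can manipulate
cond_fixture <- function(seed = 50, m = 5000, J = 3) {
  set.seed(seed)
  pi_true <- c(0.97, rep(0.03 / 7, 7))
  spec <- scenario_spec(J = J, m = m, n = 1000, overlap_corr = 0.2,
                        pi_true = pi_true, effect_sd = 0.25, seed = seed)
  sim <- simulate_stats_direct(spec)
  patmix(sim$T, theta1 = 0.03, df = 998)
}

test_that("joint covariance assembly matches an elementwise loop", {
  fit <- cond_fixture()
  cs <- conditioning_set(focal = 10, leads = c(20, 30),
                         rho = matrix(c(1, .6, .4, .6, 1, .5, .4, .5, 1), 3),
                         lead_patterns = c(2L, 8L),
                         lead_stats = fit$T[c(20, 30), ])
  for (j in 1:3) for (alt in c(FALSE, TRUE)) {
    Lam <- build_lambda(fit, cs, j, focal_alt = alt)
    mg <- fit$marginals[[j]]
    sds <- c(if (alt) mg$v[10] * mg$sd0 else mg$sd0,
             vapply(1:2, function(l) {
               q <- fit$Q[cs$lead_patterns[l], j]
               if (q == 1) mg$v[cs$leads[l]] * mg$sd0 else mg$sd0
             }, numeric(1)))
    ref <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) ref[a, b] <- sds[a] * sds[b] * cs$rho[a, b]
    expect_equal(Lam, ref, tolerance = 1e-12)
  }
})

test_that("conditional moments follow the closed form and the Schur bound", {
  # bivariate textbook case
  Lam <- matrix(c(1, 0.5, 0.5, 1), 2)
  d <- conditional_densities(0.3, lead_stats = 1.0, Lam, Lam)
  expect_equal(d$mean0, 0.5)
  expect_equal(d$var0, 0.75)
  expect_equal(d$f0, dnorm(0.3, 0.5, sqrt(0.75)))

  # trivariate: against the joint/marginal density ratio oracle
  set.seed(51)
  A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(3)
  x <- c(0.7, -0.4, 1.2)
  m0 <- patmix:::.cond_moments(S, x[-1])
  ref <- naive_conditional_logdens(x, S)
  expect_equal(dnorm(x[1], m0["mean"], sqrt(m0["var"]), log = TRUE),
               unname(ref), tolerance = 1e-10)

  # conditional variance never exceeds the marginal, strictly when rho != 0
  expect_lt(m0[["var"]], S[1, 1])
  Lam0 <- diag(c(2, 1, 1))
  m_diag <- patmix:::.cond_moments(Lam0, c(3, -3))
  expect_equal(unname(m_diag), c(0, 2))
})

test_that("conditioning with zero LD or no leads reproduces the marginal", {
  fit <- cond_fixture()
  i <- which.max(fit$post[, 8])

  # empty lead set: identical to the marginal posterior row
  cs0 <- conditioning_set(focal = i, leads = integer(0),
                          rho = matrix(1, 1, 1),
                          lead_patterns = integer(0), lead_stats = NULL)
  cp0 <- conditional_posterior(fit, cs0)
  expect_equal(unname(cp0$post), unname(fit$post[i, ]), tolerance = 1e-10)
  expect_false(cp0$flipped)

  # uncorrelated leads: densities unchanged (exact no-op on rho = 0)
  cs1 <- conditioning_set(focal = i, leads = c(1L, 2L),
                          rho = diag(3), lead_patterns = c(1L, 1L),
                          lead_stats = fit$T[1:2, ])
  cp1 <- conditional_posterior(fit, cs1)
  expect_equal(unname(cp1$post), unname(fit$post[i, ]), tolerance = 1e-10)
})

test_that("lead selection honors the distance and LD exclusion rules", {
  fit <- cond_fixture()
  m_r <- 60
  region <- seq_len(m_r)
  positions <- (seq_len(m_r) - 1L) * 1000L # 1 kb spacing
  # plant a strong omics SNP far away and one within 5 kb of the focal
  post <- fit$post
  focal <- 30L
  far <- 55L; near <- 32L
  rho <- diag(m_r)
  # study-2 signal strongest at `far`, study-3 at `near` (within 5 kb)
  fit2 <- fit
  fit2$post[region, ] <- matrix(rep(c(1, rep(0, 7)), m_r), m_r, 8, byrow = TRUE)
  fit2$post[far, ] <- c(0, 0, 0.9, 0, 0, 0, 0.1, 0)   # study 2 assoc
  fit2$post[near, ] <- c(0, 0, 0, 0.9, 0, 0, 0.1, 0)  # study 3 assoc
  fit2$a_hat[c(far, near)] <- c(3L, 4L)
  cs <- select_leads(fit2, region, positions, focal, rho = rho)
  expect_equal(cs$leads, far)
  expect_true("within_distance" %in% cs$dropped)

  # a high-LD proxy of the focal is excluded too
  rho2 <- rho; rho2[focal, far] <- rho2[far, focal] <- 0.97
  cs2 <- select_leads(fit2, region, positions, focal, rho = rho2)
  expect_length(cs2$leads, 0)
  expect_true("high_ld_proxy" %in% cs2$dropped)

  # the focal SNP being its own lead yields an empty set, flagged
  fit3 <- fit2
  fit3$post[focal, ] <- c(0, 0, 0.95, 0.0, 0, 0, 0.05, 0)
  fit3$post[far, ] <- c(1, rep(0, 7))
  fit3$post[near, ] <- c(1, rep(0, 7))
  cs3 <- select_leads(fit3, region, positions, focal, rho = rho)
  expect_length(cs3$leads, 0)
  expect_true("is_focal" %in% cs3$dropped)
})

test_that("conditional FDR correction replaces failed discoveries by 1", {
  p <- c(rep(0.9, 10), 0.5)
  failed <- c(rep(FALSE, 8), TRUE, TRUE, FALSE)
  # 10 discoveries at 0.8; two fail: (8 * 0.1 + 2) / 10
  expect_equal(conditional_fdr_correction(p, failed, 0.8), 0.28)
  # none fail: reduces to the plain estimated FDR
  expect_equal(conditional_fdr_correction(p, rep(FALSE, 11), 0.8),
               estimated_fdr(p, 0.8))
  # all fail: estimated FDR of 1
  expect_equal(conditional_fdr_correction(p, rep(TRUE, 11), 0.8), 1)
  expect_warning(out <- conditional_fdr_correction(0.5, TRUE, 0.8), "no discoveries")
  expect_true(is.na(out))
})

test_that("planted confounder regions select both distinct leads", {
  set.seed(52)
  spec <- scenario_spec(J = 4, m = 4000, n = c(1000, 500, 300, 200),
                        overlap_corr = 0.2, pi_true = c(1, rep(0, 15)),
                        block_size = 1000, seed = 99)
  sim <- simulate_geno_pheno(spec, ld_blocks = TRUE)
  fit <- patmix:::.fit_from_sim_stats(sim, c(6e-4, 8e-4, 8e-4, 4e-4) * 5, "t")
  planted <- which(sim$blocks$type != "null")
  expect_gt(length(planted), 0) # 40% of blocks carry effects by design
  b <- planted[1]
  bs <- spec$block_size
  region <- ((b - 1) * bs + 1):(b * bs)
  blk <- patmix:::.regen_block(sim, spec, sim$seed, b)
  focal <- (b - 1) * bs + sim$blocks$focal[b]
  cs <- select_leads(fit, region, patmix:::.block_positions(bs),
                     focal, geno = blk$G)
  conf <- (b - 1) * bs + c(sim$blocks$c1[b], sim$blocks$c2[b])
  expect_true(all(cs$leads %in% conf))
  expect_gt(length(cs$leads), 0)
})
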