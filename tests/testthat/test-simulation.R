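test_that("generators are seed-deterministic", {
  spec <- scenario_spec(J = 3, m = 5000, n = 1000, overlap_corr = 0.2,
                        pi_true = c(0.99, rep(0.01 / 7, 7)), seed = 5)
  a <- simulate_stats_direct(spec)
  b <- simulate_stats_direct(spec)
  expect_identical(a, b)

  spec4 <- scenario_spec(J = 4, m = 3000, n = c(1000, 500, 300, 200),
                         overlap_corr = 0.2, pi_true = c(1, rep(0, 15)),
                         block_size = 1000, seed = 6)
  g1 <- simulate_geno_pheno(spec4, ld_blocks = TRUE)
  g2 <- simulate_geno_pheno(spec4, ld_blocks = TRUE)
  expect_identical(g1$stats, g2$stats)
  expect_identical(g1$blocks, g2$blocks)
})

test_that("direct null statistics match their closed-form tail and correlation", {
  spec <- scenario_spec(J = 3, m = 4e5, n = 1000, overlap_corr = 0,
                        pi_true = c(1, rep(0, 7)), seed = 7)
  sim <- simulate_stats_direct(spec)
  # |t| > 5 under the standard normal null
  expect_lt(abs(mean(abs(sim$T) > 5) - 2 * pnorm(-5)), 1e-5)
  G <- estimate_null_correlation(sim$T)
  expect_lt(max(abs(G[upper.tri(G)])), 0.01)

  # designed overlap correlation is recovered
  spec2 <- scenario_spec(J = 3, m = 4e5, n = 1000, overlap_corr = 0.2,
                         pi_true = c(1, rep(0, 7)), seed = 8)
  G2 <- estimate_null_correlation(simulate_stats_direct(spec2)$T)
  expect_lt(max(abs(G2[upper.tri(G2)] - 0.2)), 0.02)
})

test_that("marginal alternative fractions track the pattern-implied rates", {
  pi_true <- c(0.98, 0.002, 0.002, 0.002, 0.004, 0.004, 0.004, 0.002)
  spec <- scenario_spec(J = 3, m = 2e5, n = 1000, overlap_corr = 0,
                        pi_true = pi_true, seed = 9)
  sim <- simulate_stats_direct(spec)
  theta_implied <- as.numeric(crossprod(sim$Q, pi_true))
  for (j in 1:3) {
    frac <- mean(sim$Q[sim$truth, j] == 1)
    expect_lt(abs(frac - theta_implied[j]),
              3 * sqrt(theta_implied[j] / spec$m) + 1e-4)
  }
  # truth proportions consistent with pi_true (chi-square GOF not rejected)
  counts <- tabulate(sim$truth, nbins = 8)
  gof <- suppressWarnings(chisq.test(counts, p = pi_true))
  expect_gt(gof$p.value, 1e-4)
})

test_that("null genotype-phenotype statistics follow the t distribution", {
  spec <- scenario_spec(J = 2, m = 4000, n = c(400, 400), overlap_corr = 0,
                        pi_true = c(1, 0, 0, 0), block_size = 500, seed = 10)
  sim <- simulate_geno_pheno(spec)
  ks <- suppressWarnings(
    ks.test(sim$stats$t[, 1], function(q) pt(q, df = 398)))
  expect_gt(ks$p.value, 0.01)
  # MAFs are observed from the analyzed subset, in (0, 0.5]
  expect_true(all(sim$stats$maf > 0 & sim$stats$maf <= 0.5))
})

test_that("a planted effect yields the predicted noncentrality", {
  set.seed(11)
  n <- 1000; reps <- 200
  maf <- 0.3; b <- 0.25
  tt <- replicate(reps, {
    g <- rbinom(n, 2, maf)
    y <- (g / sd(g)) * b + rnorm(n)
    st <- patmix:::.single_variant_stats(cbind(g), y)
    st$t
  })
  # per-SD effect b with unit residual error: noncentrality ~ b * sqrt(n - 1)
  expect_lt(abs(mean(tt) - b * sqrt(n - 1)), 0.3)
})

test_that("overlapping samples induce the designed null statistic correlation", {
  spec <- scenario_spec(J = 3, m = 20000, n = c(1000, 1000, 1000),
                        overlap_corr = 0.2, pi_true = c(1, rep(0, 7)),
                        block_size = 500, seed = 12)
  sim <- simulate_geno_pheno(spec)
  G <- cor(sim$stats$t)
  expect_lt(max(abs(G[upper.tri(G)] - 0.2)), 0.03)
})

test_that("planted LD triples satisfy their construction constraints", {
  spec <- scenario_spec(J = 4, m = 20000, n = c(1000, 500, 300, 200),
                        overlap_corr = 0.2, pi_true = c(1, rep(0, 15)),
                        block_size = 1000, seed = 13)
  pl <- plant_ld_blocks(spec)
  rr <- as.matrix(pl$blocks[, c("r_f1", "r_f2", "r_12")])
  expect_true(all(rr >= 0.5 & rr <= 0.8))
  expect_true(all(pl$blocks$maf_focal > 0.1))
  # composition: 20/20/60 up to rounding
  expect_equal(sum(pl$blocks$type == "null") / nrow(pl$blocks), 0.6,
               tolerance = 0.11)
  # null blocks have all-null truth; planted focals carry their patterns
  labs <- pattern_labels(make_patterns(4))
  bs <- spec$block_size
  for (b in seq_len(nrow(pl$blocks))) {
    rows <- ((b - 1) * bs + 1):(b * bs)
    if (pl$blocks$type[b] == "null") {
      expect_true(all(pl$truth[rows] == 1L))
    } else {
      focal_pat <- unname(labs[pl$truth[rows][pl$blocks$focal[b]]])
      expect_equal(focal_pat,
                   if (pl$blocks$type[b] == "A") "1010" else "1111")
    }
  }
  # triples are separated by more than the 5-kb conditioning window
  gap <- with(pl$blocks, pmin(abs(focal - c1), abs(focal - c2), abs(c1 - c2)))
  expect_true(all(gap * 200 > 5000))
})

test_that("scenario runs are reproducible end to end", {
  a <- run_scenario("1a", reps = 1, scale = 1000, seed = 3)
  b <- run_scenario("1a", reps = 1, scale = 1000, seed = 3)
  expect_identical(a$pi_hat, b$pi_hat)
})
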