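# Synthetic-data generators mirroring the statistical structure of the
# calibration scenarios: sparse joint association patterns, overlapping
# samples, and LD blocks with confounding SNPs.

# compound-symmetric correlation matrix
.cs_corr <- function(J, rho) {
  R <- matrix(rho, J, J)
  diag(R) <- 1
  R
}

#' Specify a simulation scenario
#'
#' @param J Number of studies.
#' @param m Number of SNPs (a multiple of `block_size` for genotype-based
#'   simulation).
#' @param n Per-study sample sizes (recycled to length J); genotype-based
#'   simulation draws the smaller studies as subsets of the `max(n)`
#'   subjects, so their samples overlap.
#' @param overlap_corr Pairwise correlation of the phenotype error terms
#'   (and hence of null statistics across studies sharing samples).
#' @param pi_true Length-2^J true pattern proportions in canonical pattern
#'   order (see [make_patterns()]).
#' @param effect_sd Standard deviation(s) of the normal effect-size
#'   distribution under the alternative; a vector cycles over gene regions.
#' @param block_size SNPs per gene region (default 500).
#' @param ld_r_range Target pairwise genotype correlation range for planted
#'   confounder triples (default `c(0.5, 0.8)`).
#' @param seed Default RNG seed used when a generator is called without one.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(J, m, n, overlap_corr = 0, pi_true,
                          effect_sd = 1, block_size = 500,
                          ld_r_range = c(0.5, 0.8), seed = 1L) {
  if (length(pi_true) != 2^J) stop("`pi_true` must have length 2^J")
  if (any(pi_true < 0) || abs(sum(pi_true) - 1) > 1e-8) {
    stop("`pi_true` must be on the simplex")
  }
  if (any(effect_sd <= 0)) stop("`effect_sd` must be positive")
  if (overlap_corr < 0 || overlap_corr >= 1) stop("`overlap_corr` must be in [0, 1)")
  if (length(ld_r_range) != 2L || any(abs(ld_r_range) >= 1)) {
    stop("`ld_r_range` must be two correlations inside (-1, 1)")
  }
  structure(list(J = as.integer(J), m = as.integer(m),
                 n = rep_len(as.integer(n), J), overlap_corr = overlap_corr,
                 pi_true = pi_true, effect_sd = effect_sd,
                 block_size = as.integer(block_size),
                 ld_r_range = ld_r_range, seed = as.integer(seed)),
            class = "scenario_spec")
}

# marginal per-study non-null proportions implied by pi_true
.theta_from_pi <- function(pi_true, Q) {
  as.numeric(crossprod(Q, pi_true))
}

#' Simulate association statistics directly
#'
#' Draws each SNP's true pattern from `pi_true`, then its statistic vector
#' as correlated standard normals (pairwise correlation `overlap_corr`)
#' plus, in associated studies, a mean of `sqrt(n_j) * beta` with
#' `beta ~ N(0, effect_sd^2)` — the non-centrality a single-variant test
#' of that effect would have at the study's sample size.
#'
#' @param spec A [scenario_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return List with `T` (m x J statistics), `truth` (pattern indices),
#'   and `Q`.
#' @export
simulate_stats_direct <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  J <- spec$J; m <- spec$m
  Q <- make_patterns(J)
  a <- sample.int(nrow(Q), m, replace = TRUE, prob = spec$pi_true)
  E <- matrix(stats::rnorm(m * J), m, J)
  if (spec$overlap_corr > 0) E <- E %*% chol(.cs_corr(J, spec$overlap_corr))
  Qa <- Q[a, , drop = FALSE]
  nz <- which(Qa == 1L)
  if (length(nz) > 0L) {
    colidx <- (nz - 1L) %/% m + 1L
    E[nz] <- E[nz] +
      stats::rnorm(length(nz), 0, spec$effect_sd[1L]) * sqrt(spec$n[colidx])
  }
  list(T = E, truth = a, Q = Q)
}

# observed per-study summary statistics of single-variant regressions
# g: n x p genotype matrix, y: length-n phenotype
.single_variant_stats <- function(g, y) {
  n <- length(y)
  pbar <- colMeans(g) / 2
  maf <- pmin(pbar, 1 - pbar)
  maf <- pmax(maf, 1 / (4 * n)) # monomorphic-in-subset guard
  cm <- colMeans(g)
  yc <- y - mean(y)
  Sxy <- as.numeric(crossprod(g, yc))
  Sxx <- colSums(g^2) - n * cm^2
  ok <- Sxx > 1e-12
  bhat <- ifelse(ok, Sxy / pmax(Sxx, 1e-12), 0)
  rss <- pmax(sum(yc^2) - bhat^2 * Sxx, 1e-12)
  se <- ifelse(ok, sqrt(rss / (n - 2) / pmax(Sxx, 1e-12)), 1)
  list(beta = bhat, se = se, maf = maf, t = bhat / se, n = n, df = n - 2)
}

#' Simulate genotypes and phenotypes with sample overlap
#'
#' Genotypes are Binomial(2, MAF) with MAF ~ Uniform(0.05, 0.5)
#' (independent SNPs unless `ld_blocks = TRUE`, which plants confounder
#' triples; see [plant_ld_blocks()]).  Within each gene region of
#' `block_size` SNPs, each SNP's pattern is drawn from `pi_true`; traits
#' follow additive genetic models `y_j = sum(beta * g) + e` with effect
#' sizes `N(0, effect_sd^2)` (cycling over regions) and error terms
#' correlated `overlap_corr` across traits.  Studies with `n_j < max(n)`
#' analyze subject subsets resampled from the full pool, so their samples
#' overlap.  Single-variant regression statistics are returned per study.
#'
#' @param spec A [scenario_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @param ld_blocks Plant LD confounder triples (requires `J = 4`)?
#' @return List with `stats` (matrices `beta`, `se`, `maf`, `t`, each
#'   m x J, plus vectors `n`, `df`), `truth` (pattern indices), `Q`, and
#'   for planted blocks the per-block structure (`blocks`).
#' @export
simulate_geno_pheno <- function(spec, seed = spec$seed, ld_blocks = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  J <- spec$J; m <- spec$m; bs <- spec$block_size
  if (m %% bs != 0L) stop("`m` must be a multiple of `block_size`")
  nblk <- m %/% bs
  if (ld_blocks && J != 4L) stop("LD confounder triples are a 4-study design")
  n_total <- max(spec$n)
  Q <- make_patterns(J)
  chR <- chol(.cs_corr(J, spec$overlap_corr))

  set.seed(seed)
  subsets <- lapply(spec$n, function(nj) {
    if (nj == n_total) seq_len(n_total) else sample.int(n_total, nj)
  })
  types <- if (ld_blocks) .block4_types(nblk) else rep("generic", nblk)

  beta <- se <- maf <- tst <- matrix(0, m, J)
  truth <- integer(m)
  blocks <- vector("list", nblk)
  for (b in seq_len(nblk)) {
    rows <- ((b - 1L) * bs + 1L):(b * bs)
    bseed <- .sub_seed(seed, b, 1L)
    blk <- if (ld_blocks) {
      .gen_block4(bseed, types[b], n_total, bs, spec$ld_r_range, chR)
    } else {
      .gen_block_generic(bseed, n_total, bs, spec, Q, chR,
                         sd_b = spec$effect_sd[(b - 1L) %% length(spec$effect_sd) + 1L])
    }
    truth[rows] <- blk$truth
    for (j in seq_len(J)) {
      st <- .single_variant_stats(blk$G[subsets[[j]], , drop = FALSE],
                                  blk$Y[subsets[[j]], j])
      beta[rows, j] <- st$beta; se[rows, j] <- st$se
      maf[rows, j] <- st$maf; tst[rows, j] <- st$t
    }
    blocks[[b]] <- blk$meta
  }
  list(stats = list(beta = beta, se = se, maf = maf, t = tst,
                    n = spec$n, df = spec$n - 2L),
       truth = truth, Q = Q, types = types,
       blocks = if (ld_blocks) do.call(rbind, blocks) else NULL,
       subsets = subsets, seed = seed)
}

# generic gene region: independent SNPs, patterns from pi_true
.gen_block_generic <- function(bseed, n_total, bs, spec, Q, chR, sd_b) {
  set.seed(bseed)
  J <- spec$J
  mafs <- stats::runif(bs, 0.05, 0.5)
  G <- matrix(stats::rbinom(n_total * bs, 2L, rep(mafs, each = n_total)),
              n_total, bs)
  a <- sample.int(nrow(Q), bs, replace = TRUE, prob = spec$pi_true)
  B <- matrix(0, bs, J)
  nz <- Q[a, , drop = FALSE] == 1L
  B[nz] <- stats::rnorm(sum(nz), 0, sd_b)
  E <- matrix(stats::rnorm(n_total * J), n_total, J) %*% chR
  Y <- E
  if (any(nz)) Y <- G %*% B + E
  list(G = G, Y = Y, truth = a, meta = NULL)
}

# block-type assignment for the LD-confounder design: 20% with a focal SNP
# of pattern (1,0,1,0) plus confounders (1,1,0,0)/(0,1,1,1); 20% with a
# focal (1,1,1,1) plus confounders (0,1,0,0)/(0,0,1,0); 60% all-null
.block4_types <- function(nblk) {
  nA <- max(1L, round(0.2 * nblk)); nB <- max(1L, round(0.2 * nblk))
  sample(rep(c("A", "B", "null"), times = c(nA, nB, nblk - nA - nB)))
}

.block4_patterns <- function(type) {
  if (type == "A") c(focal = "1010", c1 = "1100", c2 = "0111")
  else c(focal = "1111", c1 = "0100", c2 = "0010")
}

# one LD-confounder block: genotypes, planted triple, phenotypes.
# Seed-deterministic so the block can be regenerated for conditional
# analysis without storing genotypes.
.gen_block4 <- function(bseed, type, n_total, bs, ld_range, chR) {
  set.seed(bseed)
  J <- 4L
  Q <- make_patterns(J)
  labs <- pattern_labels(Q)
  mafs <- stats::runif(bs, 0.05, 0.5)
  # triple positions well separated (usable as conditioning leads)
  repeat {
    trip <- sort(sample(seq(21L, bs - 20L), 3L))
    if (min(diff(trip)) > 40L) break
  }
  ids <- sample(trip)
  focal <- ids[1L]; c1 <- ids[2L]; c2 <- ids[3L]
  mafs[focal] <- stats::runif(1L, 0.1, 0.5)
  G <- matrix(stats::rbinom(n_total * bs, 2L, rep(mafs, each = n_total)),
              n_total, bs)
  truth <- rep(1L, bs)
  # the confounding-SNP triple is a genotypic structure present in every
  # region; only 40% of regions carry effects on it.  Built as a chain
  # a -> b -> c (copy-and-resample toggling) in a random order, so the two
  # directly coupled pairs sit in the upper part of the target range and
  # the indirect pair (correlation ~ the product) spans its lower part —
  # all three pairwise correlations land inside `ld_range`.
  maf_f <- mafs[focal]
  ok <- FALSE
  for (outer in 1:5) {
    ga <- if (outer == 1L) G[, focal] else stats::rbinom(n_total, 2L, maf_f)
    for (attempt in 1:30) {
      r_t <- stats::runif(2L, 0.65, 0.80)
      mk <- function(gsrc, r) {
        g <- gsrc
        swap <- stats::runif(n_total) > r
        g[swap] <- stats::rbinom(sum(swap), 2L, maf_f)
        g
      }
      gb <- mk(ga, r_t[1L])
      gc <- mk(gb, r_t[2L])
      chain_order <- sample(3L)
      trip_cols <- c(focal, c1, c2)[chain_order]
      gg <- list(ga, gb, gc)
      rr_pair <- function(u, v) stats::cor(gg[[u]], gg[[v]])
      # realized correlations indexed back to (focal,c1), (focal,c2), (c1,c2)
      pos_of <- order(chain_order)
      rr <- c(rr_pair(pos_of[1L], pos_of[2L]),
              rr_pair(pos_of[1L], pos_of[3L]),
              rr_pair(pos_of[2L], pos_of[3L]))
      if (all(rr >= ld_range[1L] & rr <= ld_range[2L])) { ok <- TRUE; break }
    }
    if (ok) break
  }
  if (!ok) warning("LD target not reached after retries; using last draw")
  G[, trip_cols[1L]] <- ga; G[, trip_cols[2L]] <- gb; G[, trip_cols[3L]] <- gc
  meta <- data.frame(type = type, focal = focal, c1 = c1, c2 = c2,
                     maf_focal = maf_f,
                     r_f1 = rr[1L], r_f2 = rr[2L], r_12 = rr[3L])
  if (type != "null") {
    pat <- .block4_patterns(type)
    truth[focal] <- match(pat["focal"], labs)
    truth[c1] <- match(pat["c1"], labs)
    truth[c2] <- match(pat["c2"], labs)
  }
  E <- matrix(stats::rnorm(n_total * J), n_total, J) %*% chR
  Y <- E
  if (type != "null") {
    # effect sizes are per standard deviation of genotype dosage, so a
    # given magnitude explains the same trait variance at any MAF
    for (s in c(focal, c1, c2)) {
      qs <- Q[truth[s], ]
      gs <- G[, s] / stats::sd(G[, s])
      for (j in which(qs == 1L)) {
        b_sj <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.1, 0.4)
        Y[, j] <- Y[, j] + gs * b_sj
      }
    }
  }
  list(G = G, Y = Y, truth = truth, meta = meta)
}

#' Plant LD blocks with confounding SNP triples
#'
#' Generates the region structure of the LD-confounder design: gene regions
#' of `block_size` consecutive SNPs, each planted (in 40% of blocks) with a
#' focal trait-associated SNP (MAF > 0.1) and two confounding SNPs in
#' moderate-to-strong mutual LD (all pairwise genotype correlations inside
#' `ld_r_range`); the remaining blocks are entirely null.  Returns the
#' realized structure without the genotype matrices (those are regenerated
#' on demand from the per-block seeds).
#'
#' @param spec A [scenario_spec()] with `J = 4`.
#' @param seed RNG seed (default `spec$seed`).
#' @return List with `blocks` (data frame: type, triple indices within the
#'   block, focal MAF, realized pairwise correlations), `truth` (pattern
#'   index per SNP, genome-wide), `types`, and `positions` (base-pair
#'   positions within a block).
#' @export
plant_ld_blocks <- function(spec, seed = spec$seed) {
  sim <- simulate_geno_pheno(spec, seed = seed, ld_blocks = TRUE)
  list(blocks = sim$blocks, truth = sim$truth, types = sim$types,
       positions = .block_positions(spec$block_size))
}

# 1-based base-pair positions of the SNPs within a block (200 bp spacing,
# so the planted triples sit far outside the 5-kb exclusion window)
.block_positions <- function(bs) {
  (seq_len(bs) - 1L) * 200L + 1L
}

#' Run a named calibration scenario end to end
#'
#' Executes the full pipeline on synthetic data: generate statistics, fit
#' the pattern mixture, and score the results against the planted truth.
#' Scenarios:
#' * `"1a"`, `"1b"` — directly simulated statistics for J = 3 studies
#'   (10 million SNPs at `scale = 1`) with sparse / very sparse patterns;
#'   reports the recovered pattern proportions.
#' * `"2"` — genotype-based, J = 3 correlated studies (1 million SNPs at
#'   `scale = 1`), region-varying effect variances; reports FDR and power.
#' * `"3"` — genotype-based, J = 5 correlated studies.
#' * `"4a"`, `"4b"`, `"4c"` — the LD-confounder design (J = 4, 100 blocks
#'   of 1000 SNPs at `scale = 1`) with correctly / 10-fold under- /
#'   10-fold over-specified marginal proportions; reports true and
#'   estimated FDR and power for the all-associated pattern before and
#'   after conditional analysis at probability cutoffs 0.8 and 0.9.
#'
#' @param name Scenario name.
#' @param reps Number of replicates.
#' @param scale Down-scaling factor on the number of SNPs (scenario 1-3)
#'   or blocks (scenario 4).
#' @param seed Base RNG seed; every replicate derives its own sub-seed.
#' @param mode `"t"` or `"p"` input statistics (scenarios 1-3).
#' @param correlated For scenario 1: simulate pairwise statistic
#'   correlation 0.2 instead of independent studies.
#' @param theta_mult Multiplier applied to the correctly specified marginal
#'   proportions when fitting (scenario 2 robustness checks; scenarios
#'   4b/4c set 0.1 / 10 internally).
#' @return List of class `patmix_scenario` with per-replicate and averaged
#'   metrics.
#' @export
run_scenario <- function(name = c("1a", "1b", "2", "3", "4a", "4b", "4c"),
                         reps = 1L, scale = 1, seed = 1L,
                         mode = c("t", "p"), correlated = FALSE,
                         theta_mult = 1) {
  name <- match.arg(name)
  mode <- match.arg(mode)
  out <- switch(
    name,
    "1a" = , "1b" = .run_scenario1(name, reps, scale, seed, mode, correlated),
    "2" = .run_scenario23(3L, reps, scale, seed, mode, theta_mult),
    "3" = .run_scenario23(5L, reps, scale, seed, mode, theta_mult),
    "4a" = .run_scenario4(reps, scale, seed, 1),
    "4b" = .run_scenario4(reps, scale, seed, 0.1),
    "4c" = .run_scenario4(reps, scale, seed, 10)
  )
  out$name <- name
  class(out) <- "patmix_scenario"
  out
}

#' @export
print.patmix_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: %d replicate(s)\n", x$name, x$reps))
  if (!is.null(x$pi_hat_mean_pct)) {
    print(round(rbind(true_pct = 100 * x$pi_true,
                      estimate_pct = x$pi_hat_mean_pct), 4))
  }
  if (!is.null(x$metrics)) print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

# pattern proportions for the sparse three-study designs (canonical order)
.pi_scenario1 <- function(name) {
  if (name == "1a") {
    c(1 - 3 * 7e-4 - 3 * 2e-4 - 1e-4, 7e-4, 7e-4, 7e-4, 2e-4, 2e-4, 2e-4, 1e-4)
  } else {
    # very sparse associations for the third trait
    p <- c(NA, 7e-4, 7e-4, 7e-6, 2e-4, 2e-6, 2e-6, 1e-6)
    p[1] <- 1 - sum(p[-1])
    p
  }
}

.run_scenario1 <- function(name, reps, scale, seed, mode, correlated) {
  m <- round(1e7 / scale)
  n_eq <- 1000L
  pi_true <- .pi_scenario1(name)
  spec <- scenario_spec(J = 3, m = m, n = n_eq,
                        overlap_corr = if (correlated) 0.2 else 0,
                        pi_true = pi_true, effect_sd = 1, seed = seed)
  Q <- make_patterns(3)
  theta1 <- .theta_from_pi(pi_true, Q)
  df_stat <- n_eq - 2L
  pi_hat <- matrix(0, reps, nrow(Q), dimnames = list(NULL, pattern_labels(Q)))
  for (r in seq_len(reps)) {
    sim <- simulate_stats_direct(spec, seed = .sub_seed(seed, r * 1009L, 0L))
    fit <- if (mode == "t") {
      patmix(sim$T, theta1 = theta1, mode = "t", df = df_stat)
    } else {
      patmix(pmax(2 * stats::pt(-abs(sim$T), df = df_stat), 1e-300),
             theta1 = theta1, mode = "p")
    }
    pi_hat[r, ] <- fit$pi
  }
  list(reps = reps, m = m, pi_true = pi_true,
       pi_hat = pi_hat, pi_hat_mean_pct = 100 * colMeans(pi_hat))
}

# truth-scored FDR/power for a collapsed pattern group at one cutoff
.score_group <- function(p_group, is_true, cutoff) {
  disc <- p_group >= cutoff
  n_disc <- sum(disc)
  data.frame(
    cutoff = cutoff, n_disc = n_disc,
    true_fdr = if (n_disc > 0) sum(disc & !is_true) / n_disc else NA_real_,
    est_fdr = if (n_disc > 0) estimated_fdr(p_group, cutoff) else NA_real_,
    power = sum(disc & is_true) / max(sum(is_true), 1L))
}

# pattern proportions for the genotype-based designs: the per-class totals
# (one / two / all traits associated) are split equally over the patterns
# of each class, reproducing the stated marginal proportions
.pi_scenario23 <- function(J) {
  Q <- make_patterns(J)
  nass <- rowSums(Q)
  p <- numeric(nrow(Q))
  if (J == 3L) {
    p[nass == 1] <- 5e-3 / 3
    p[nass == 2] <- 5e-4 / 3
    p[nass == 3] <- 5e-4
  } else {
    p[nass == 1] <- 5e-4
    p[nass >= 2] <- 1e-4
  }
  p[1] <- 1 - sum(p[-1])
  p
}

.run_scenario23 <- function(J, reps, scale, seed, mode, theta_mult) {
  bs <- 500L
  m <- max(2L, round(1e6 / scale / bs)) * bs
  pi_true <- .pi_scenario23(J)
  effect_sd <- if (J == 3L) sqrt(c(0.25, 0.5, 1)) else 1
  spec <- scenario_spec(J = J, m = m, n = 1000L, overlap_corr = 0.2,
                        pi_true = pi_true, effect_sd = effect_sd,
                        block_size = bs, seed = seed)
  Q <- make_patterns(J)
  K <- nrow(Q)
  theta1 <- .theta_from_pi(pi_true, Q) * theta_mult
  per_rep <- list()
  for (r in seq_len(reps)) {
    sim <- simulate_geno_pheno(spec, seed = .sub_seed(seed, r * 1009L, 0L))
    fit <- .fit_from_sim_stats(sim, theta1, mode)
    p_all <- fit$post[, K]
    p_any <- 1 - fit$post[, 1L]
    sc <- rbind(
      cbind(group = "all_traits",
            rbind(.score_group(p_all, sim$truth == K, 0.8),
                  .score_group(p_all, sim$truth == K, 0.9))),
      cbind(group = "any_trait",
            rbind(.score_group(p_any, sim$truth != 1L, 0.8),
                  .score_group(p_any, sim$truth != 1L, 0.9))))
    sc$rep <- r
    per_rep[[r]] <- sc
  }
  all_reps <- do.call(rbind, per_rep)
  metrics <- stats::aggregate(
    cbind(true_fdr, est_fdr, power, n_disc) ~ group + cutoff, data = all_reps,
    FUN = mean, na.action = stats::na.pass, na.rm = TRUE)
  list(reps = reps, m = m, pi_true = pi_true, theta1_fit = theta1,
       metrics = metrics, per_rep = all_reps)
}

# moderated-t (or P-value) fit from simulated genotype-based statistics
.fit_from_sim_stats <- function(sim, theta1, mode = "t") {
  st <- sim$stats
  J <- ncol(st$beta)
  if (mode == "p") {
    P <- matrix(0, nrow(st$t), J)
    for (j in seq_len(J)) P[, j] <- pmax(2 * stats::pt(-abs(st$t[, j]), df = st$df[j]), 1e-300)
    return(patmix(P, theta1 = theta1, mode = "p"))
  }
  X <- matrix(0, nrow(st$beta), J); W <- matrix(1, nrow(st$beta), J)
  dfs <- numeric(J)
  for (j in seq_len(J)) {
    mod <- moderate_tstats(st$beta[, j], st$se[, j], st$maf[, j],
                           st$n[j], st$df[j])
    X[, j] <- mod$t_mod; W[, j] <- mod$w; dfs[j] <- mod$d_total
  }
  patmix(X, theta1 = theta1, mode = "t", df = dfs, weights = W)
}

.run_scenario4 <- function(reps, scale, seed, theta_mult,
                           cutoffs = c(0.8, 0.9)) {
  bs <- 1000L
  nblk <- max(5L, round(100 / scale))
  m <- nblk * bs
  J <- 4L
  Q <- make_patterns(J)
  K <- nrow(Q)
  labs <- pattern_labels(Q)
  # marginal non-null proportions implied by the block composition
  patA <- .block4_patterns("A"); patB <- .block4_patterns("B")
  qsum <- function(pats) {
    Reduce(`+`, lapply(pats, function(s) Q[match(s, labs), ]))
  }
  theta_true <- (0.2 * qsum(patA) + 0.2 * qsum(patB)) / bs
  theta1 <- theta_true * theta_mult
  pi_dummy <- c(1, rep(0, K - 1L)) # patterns are planted, not drawn
  spec <- scenario_spec(J = J, m = m, n = c(1000L, 500L, 300L, 200L),
                        overlap_corr = 0.2, pi_true = pi_dummy,
                        block_size = bs, seed = seed)
  per_rep <- list()
  for (r in seq_len(reps)) {
    rep_seed <- .sub_seed(seed, r * 1009L, 0L)
    sim <- simulate_geno_pheno(spec, seed = rep_seed, ld_blocks = TRUE)
    fit <- .fit_from_sim_stats(sim, theta1, mode = "t")
    # the candidate ("index") SNPs are the known trait-associated SNPs:
    # one planted focal SNP per region, evaluated against its two
    # confounding SNPs in the same region
    off <- (seq_len(nblk) - 1L) * bs
    focal_rows <- off + sim$blocks$focal
    lead_rows <- cbind(off + sim$blocks$c1, off + sim$blocks$c2)
    pK <- fit$post[focal_rows, K]
    is_true <- sim$truth[focal_rows] == K
    # conditional pass for every focal discovered at the loosest cutoff
    disc_all <- which(pK >= min(cutoffs))
    retained <- rep(TRUE, nblk)
    for (b in disc_all) {
      blk <- .regen_block(sim, spec, rep_seed, b)
      trip_local <- c(sim$blocks$focal[b], sim$blocks$c1[b], sim$blocks$c2[b])
      cs <- conditioning_set(
        focal = focal_rows[b], leads = lead_rows[b, ],
        rho = stats::cor(blk$G[, trip_local]),
        lead_patterns = fit$a_hat[lead_rows[b, ]],
        lead_stats = fit$T[lead_rows[b, ], , drop = FALSE])
      retained[b] <- conditional_posterior(fit, cs)$a_hat == K
    }
    rows <- lapply(cutoffs, function(co) {
      before <- .score_group(pK, is_true, co)
      disc <- pK >= co
      n_disc <- sum(disc)
      after <- data.frame(
        cutoff = co, n_disc = n_disc,
        true_fdr = if (n_disc > 0) sum(disc & retained & !is_true) / n_disc else NA_real_,
        est_fdr = if (n_disc > 0) {
          conditional_fdr_correction(pK, failed = !retained, lambda = co)
        } else NA_real_,
        power = sum(disc & retained & is_true) / max(sum(is_true), 1L))
      rbind(cbind(stage = "before", before), cbind(stage = "after", after))
    })
    sc <- do.call(rbind, rows)
    sc$rep <- r
    per_rep[[r]] <- sc
  }
  all_reps <- do.call(rbind, per_rep)
  metrics <- stats::aggregate(
    cbind(true_fdr, est_fdr, power, n_disc) ~ stage + cutoff, data = all_reps,
    FUN = mean, na.action = stats::na.pass, na.rm = TRUE)
  list(reps = reps, m = m, n_blocks = nblk, theta1_fit = theta1,
       metrics = metrics, per_rep = all_reps)
}

# deterministically rebuild one block's genotypes from its sub-seed
.regen_block <- function(sim, spec, rep_seed, b) {
  .gen_block4(.sub_seed(rep_seed, b, 1L), sim$types[b], max(spec$n),
              spec$block_size, spec$ld_r_range,
              chol(.cs_corr(spec$J, spec$overlap_corr)))
}
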