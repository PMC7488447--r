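#' Select lead omics SNPs for conditional analysis of a focal SNP
#'
#' Within a region, identifies for each omics study the SNP most strongly
#' associated with that study's trait (largest collapsed posterior
#' probability of association; ties resolved toward the smaller P value)
#' and keeps it as a conditioning lead unless it is the focal SNP itself,
#' lies within `dist_kb` of the focal SNP, or has genotype `r^2 > r2_max`
#' with it (in either case individual associations cannot be separated, so
#' conditioning on it would be meaningless).
#'
#' @param fit A fitted [patmix()] model covering the region's SNPs.
#' @param region Integer row indices (into the fit) of the region's SNPs.
#' @param positions Base-pair positions of the region's SNPs (1-based,
#'   same order as `region`).
#' @param focal Row index (into the fit) of the focal SNP; must be in
#'   `region`.
#' @param rho Optional correlation matrix among the region SNPs (signed
#'   genotype correlation, ordered like `region`).
#' @param geno Optional n x length(region) genotype matrix from which
#'   correlations are computed when `rho` is missing.
#' @param omics Study indices treated as omics studies (default all but
#'   study 1).
#' @param dist_kb Exclusion distance in kb (default 5).
#' @param r2_max Exclusion LD threshold on r^2 (default 0.9).
#' @param pvalues Optional matrix (length(region) x J) of P values used
#'   only for tie-breaking.
#' @return Object of class `patmix_condset`: a list with `focal`, `leads`
#'   (possibly empty), `rho` (correlations among focal + leads),
#'   `lead_patterns` (their most probable patterns), `lead_stats`
#'   (their statistic rows), and `dropped` (candidates excluded and why).
#' @export
select_leads <- function(fit, region, positions, focal, rho = NULL,
                         geno = NULL, omics = NULL, dist_kb = 5,
                         r2_max = 0.9, pvalues = NULL) {
  stopifnot(inherits(fit, "patmix"), length(positions) == length(region))
  fi <- match(focal, region)
  if (is.na(fi)) stop("`focal` must be one of the `region` indices")
  if (is.null(omics)) omics <- setdiff(seq_len(fit$J), 1L)
  if (is.null(rho) && is.null(geno)) {
    stop("supply either `rho` or `geno` to evaluate LD with the focal SNP")
  }
  get_rho <- function(a, b) { # local region indices
    if (!is.null(rho)) return(rho[a, b])
    stats::cor(geno[, a], geno[, b])
  }
  post_r <- fit$post[region, , drop = FALSE]
  cand <- integer(0)
  for (j in omics) {
    pj <- rowSums(post_r[, fit$Q[, j] == 1L, drop = FALSE])
    top <- which(pj == max(pj))
    if (length(top) > 1L && !is.null(pvalues)) {
      top <- top[which.min(pvalues[top, j])]
    }
    cand <- c(cand, top[1L])
  }
  cand <- unique(cand)
  dropped <- character(0)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    ci <- cand[i]
    if (ci == fi) { dropped <- c(dropped, "is_focal"); next }
    if (abs(positions[ci] - positions[fi]) <= dist_kb * 1000) {
      dropped <- c(dropped, "within_distance"); next
    }
    if (get_rho(ci, fi)^2 > r2_max) {
      dropped <- c(dropped, "high_ld_proxy"); next
    }
    keep[i] <- TRUE
  }
  leads_local <- cand[keep]
  idx <- c(fi, leads_local)
  R <- diag(length(idx))
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a < b) R[a, b] <- R[b, a] <- get_rho(idx[a], idx[b])
  }
  structure(
    list(focal = focal, leads = region[leads_local], rho = R,
         lead_patterns = fit$a_hat[region[leads_local]],
         lead_stats = fit$T[region[leads_local], , drop = FALSE],
         dropped = dropped),
    class = "patmix_condset"
  )
}

#' Build a conditioning set from explicit components
#'
#' Lower-level constructor for [conditional_posterior()] when the lead SNPs
#' and their genotype correlations are supplied directly rather than
#' selected by [select_leads()].
#'
#' @param focal Row index of the focal SNP in the fit.
#' @param leads Row indices of the lead SNPs (may be empty).
#' @param rho (1 + L) x (1 + L) genotype correlation matrix ordered as
#'   (focal, leads); symmetric with unit diagonal.
#' @param lead_patterns Pattern index assigned to each lead (defaults to
#'   the fit's most probable pattern when used via [conditional_posterior()]).
#' @param lead_stats L x J matrix of the leads' statistics.
#' @return Object of class `patmix_condset`.
#' @export
conditioning_set <- function(focal, leads, rho, lead_patterns, lead_stats) {
  L <- length(leads)
  rho <- as.matrix(rho)
  stopifnot(.is_square(rho), nrow(rho) == 1L + L,
            max(abs(rho - t(rho))) < 1e-8, all(abs(diag(rho) - 1) < 1e-8))
  if (focal %in% leads) stop("the focal SNP cannot be its own lead")
  if (L > 0L) {
    lead_stats <- as.matrix(lead_stats)
    stopifnot(nrow(lead_stats) == L, length(lead_patterns) == L)
  }
  structure(list(focal = focal, leads = leads, rho = rho,
                 lead_patterns = lead_patterns,
                 lead_stats = if (L > 0L) as.matrix(lead_stats) else NULL,
                 dropped = character(0)),
            class = "patmix_condset")
}

#' Joint covariance of focal and lead statistics in one study
#'
#' Assembles the (1 + L) x (1 + L) covariance of the statistic vector
#' (focal, leads) in study `j` under the multivariate-normal model:
#' diagonal entries are the pattern-specific variances
#' `v^(2q) * d/(d-2)` (the focal entry under `focal_alt`, each lead under
#' its assigned pattern), off-diagonals are the products of the two SNPs'
#' standard deviations and their genotype correlation.  A ridge of 1e-6 is
#' added to the lead block if assembly leaves the matrix indefinite.
#'
#' @param fit A fitted [patmix()] model (t-mode or P-mode; the normal
#'   approximation of the statistics is used either way).
#' @param cs A conditioning set from [select_leads()] or
#'   [conditioning_set()].
#' @param study Study index j.
#' @param focal_alt Is the focal SNP associated in study j under the
#'   pattern being evaluated (`q_kj = 1`)?
#' @return Symmetric covariance matrix.
#' @export
build_lambda <- function(fit, cs, study, focal_alt) {
  j <- study
  mg <- fit$marginals[[j]]
  if (mg$mode != "t") stop("conditional analysis requires a t-mode fit")
  v_focal <- mg$v[cs$focal]
  sd_f <- if (focal_alt) v_focal * mg$sd0 else mg$sd0
  L <- length(cs$leads)
  sd_leads <- numeric(L)
  for (l in seq_len(L)) {
    q_lead <- fit$Q[cs$lead_patterns[l], j]
    v_lead <- mg$v[cs$leads[l]]
    sd_leads[l] <- if (q_lead == 1L) v_lead * mg$sd0 else mg$sd0
  }
  sds <- c(sd_f, sd_leads)
  Lam <- cs$rho * tcrossprod(sds)
  ev <- eigen(Lam, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    warning("assembled covariance is indefinite; adding a 1e-6 ridge to the lead block")
    if (L > 0L) diag(Lam)[-1L] <- diag(Lam)[-1L] + 1e-6
  }
  Lam
}

# conditional mean and variance of the focal entry given the leads
.cond_moments <- function(Lambda, lead_stats_j) {
  L <- nrow(Lambda) - 1L
  if (L == 0L) return(c(mean = 0, var = Lambda[1L, 1L]))
  L12 <- Lambda[1L, -1L, drop = FALSE]
  L22 <- Lambda[-1L, -1L, drop = FALSE]
  sol <- tryCatch(solve(L22, t(L12)), error = function(e) NULL)
  if (is.null(sol)) {
    diag(L22) <- diag(L22) + 1e-6
    sol <- solve(L22, t(L12))
  }
  mu <- as.numeric(crossprod(sol, lead_stats_j))
  v <- Lambda[1L, 1L] - as.numeric(L12 %*% sol)
  c(mean = mu, var = max(v, .Machine$double.eps))
}

#' Conditional null and alternative densities of a focal statistic
#'
#' Given the joint covariances of (focal, leads) under the focal-null and
#' focal-alternative models, computes the univariate conditional normal
#' density of the focal statistic given the observed lead statistics:
#' mean `L12 L22^-1 t_leads`, variance `L11 - L12 L22^-1 L21` (a Schur
#' complement, never exceeding the marginal variance).
#'
#' @param t_focal Focal SNP statistic in the study.
#' @param lead_stats Lead statistics in the study (length L).
#' @param Lambda0,Lambda1 Covariances from [build_lambda()] with
#'   `focal_alt = FALSE` / `TRUE`.
#' @param log Return log densities?
#' @return List with `f0`, `f1` and the conditional moments
#'   `mean0`, `var0`, `mean1`, `var1`.
#' @export
conditional_densities <- function(t_focal, lead_stats, Lambda0, Lambda1,
                                  log = FALSE) {
  m0 <- .cond_moments(Lambda0, lead_stats)
  m1 <- .cond_moments(Lambda1, lead_stats)
  list(f0 = stats::dnorm(t_focal, m0["mean"], sqrt(m0["var"]), log = log),
       f1 = stats::dnorm(t_focal, m1["mean"], sqrt(m1["var"]), log = log),
       mean0 = unname(m0["mean"]), var0 = unname(m0["var"]),
       mean1 = unname(m1["mean"]), var1 = unname(m1["var"]))
}

# drop the most collinear lead (largest mean |rho| with the other leads)
.drop_collinear_lead <- function(cs) {
  L <- length(cs$leads)
  if (L == 0L) return(cs)
  if (L == 1L) worst <- 1L else {
    Rl <- abs(cs$rho[-1L, -1L, drop = FALSE]); diag(Rl) <- 0
    worst <- which.max(rowSums(Rl))
  }
  keep <- setdiff(seq_len(L), worst)
  conditioning_set(cs$focal, cs$leads[keep], cs$rho[c(1L, 1L + keep), c(1L, 1L + keep)],
                   cs$lead_patterns[keep], cs$lead_stats[keep, , drop = FALSE])
}

#' Re-assess a focal SNP's pattern probabilities conditional on lead SNPs
#'
#' Rebuilds the focal SNP's per-study null and alternative densities as
#' conditional normal densities given the lead SNPs' statistics (partitioned
#' multivariate-normal conditioning on the joint covariance from
#' [build_lambda()]), combines them across studies exactly as in the
#' marginal pass (through the null correlation `Gamma`, or as products when
#' the fit is independent-mode), and evaluates the posterior with the
#' genome-wide pattern proportions held fixed.  An association that was
#' driven only by LD with a lead SNP loses its alternative support once the
#' lead is conditioned on.
#'
#' With an empty lead set the result equals the marginal posterior row.
#'
#' @param fit A fitted t-mode [patmix()] model.
#' @param cs Conditioning set from [select_leads()] or [conditioning_set()].
#' @return List with `post` (length-K posterior), `a_hat`, `logD`
#'   (pattern log densities), and `flipped` (did the most probable pattern
#'   change relative to the marginal pass?).
#' @export
conditional_posterior <- function(fit, cs) {
  stopifnot(inherits(fit, "patmix"), inherits(cs, "patmix_condset"))
  if (fit$mode != "t") stop("conditional analysis requires a t-mode fit")
  J <- fit$J; K <- fit$K
  t_focal <- fit$T[cs$focal, ]
  # per-study conditional moments under focal-null and focal-alternative
  mom <- matrix(0, J, 4L, dimnames = list(NULL, c("mu0", "var0", "mu1", "var1")))
  for (j in seq_len(J)) {
    cs_j <- cs
    repeat {
      L0 <- build_lambda(fit, cs_j, j, focal_alt = FALSE)
      L1 <- build_lambda(fit, cs_j, j, focal_alt = TRUE)
      if (length(cs_j$leads) == 0L) {
        res <- list(m0 = c(mean = 0, var = L0[1L, 1L]),
                    m1 = c(mean = 0, var = L1[1L, 1L]))
        break
      }
      res <- tryCatch({
        m0 <- .cond_moments(L0, cs_j$lead_stats[, j])
        m1 <- .cond_moments(L1, cs_j$lead_stats[, j])
        list(m0 = m0, m1 = m1)
      }, error = function(e) NULL)
      if (!is.null(res)) break
      warning("singular lead block in study ", j, "; dropping the most collinear lead")
      cs_j <- .drop_collinear_lead(cs_j)
    }
    mom[j, ] <- c(res$m0, res$m1)
  }
  logD <- numeric(K)
  G <- if (fit$independent || is.null(fit$Gamma)) diag(J) else fit$Gamma
  for (k in seq_len(K)) {
    qk <- fit$Q[k, ]
    mu <- ifelse(qk == 1L, mom[, "mu1"], mom[, "mu0"])
    sds <- sqrt(ifelse(qk == 1L, mom[, "var1"], mom[, "var0"]))
    if (fit$independent) {
      logD[k] <- sum(stats::dnorm(t_focal, mu, sds, log = TRUE))
    } else {
      S <- G * tcrossprod(sds)
      z <- t_focal - mu
      ch <- chol(S)
      logD[k] <- -J / 2 * log(2 * pi) - sum(log(diag(ch))) -
        0.5 * sum(backsolve(ch, z, transpose = TRUE)^2)
    }
  }
  lw <- logD + log(pmax(fit$pi, .Machine$double.xmin))
  lw[fit$pi == 0] <- -Inf
  post <- exp(lw - max(lw)); post <- post / sum(post)
  names(post) <- fit$labels
  a_hat <- which.max(post)
  list(post = post, a_hat = a_hat, logD = logD,
       flipped = a_hat != fit$a_hat[cs$focal])
}

#' Estimated FDR corrected by a conditional-analysis pass
#'
#' After conditional analysis, a discovery that no longer carries its
#' association pattern counts as an estimated false discovery: its
#' contribution to the numerator of the estimated FDR is replaced by 1.
#' The denominator stays the number of discoveries before the conditional
#' pass, so pre- and post-conditioning rates are directly comparable.
#'
#' @param p_hat Collapsed posterior probabilities (marginal pass) for all
#'   SNPs considered.
#' @param failed Logical vector: did the SNP fail the conditional pass
#'   (most probable pattern changed)?  Entries for non-discoveries are
#'   ignored.
#' @param lambda Probability threshold that defined the discoveries.
#' @return Corrected estimated FDR, or `NA` when there were no discoveries.
#' @export
conditional_fdr_correction <- function(p_hat, failed, lambda) {
  .stopifnot_prob(lambda, "lambda")
  stopifnot(length(failed) == length(p_hat))
  disc <- p_hat >= lambda
  n <- sum(disc)
  if (n == 0L) {
    warning("no discoveries at this threshold; corrected FDR is undefined")
    return(NA_real_)
  }
  (sum((1 - p_hat)[disc & !failed]) + sum(disc & failed)) / n
}
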