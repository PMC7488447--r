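# internal numerical helpers

# row-wise log-sum-exp of a matrix; returns vector of length nrow(x)
.logsumexp_rows <- function(x) {
  mx <- apply(x, 1L, max)
  mx + log(rowSums(exp(x - mx)))
}

# project a symmetric matrix to the nearest correlation-like PSD matrix:
# clip eigenvalues below `eps`, reconstruct, rescale to unit diagonal
.project_psd_corr <- function(x, eps = 1e-8) {
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) >= eps) {
    diag(x) <- 1
    return(x)
  }
  v <- pmax(e$values, eps)
  y <- e$vectors %*% (v * t(e$vectors))
  y <- stats::cov2cor(y)
  diag(y) <- 1
  (y + t(y)) / 2
}

.is_square <- function(x) is.matrix(x) && nrow(x) == ncol(x)

# variance ratio d/(d-2) of a t distribution, with the normal limit at d = Inf
.t_var_ratio <- function(df) {
  if (any(df <= 2)) {
    stop("degrees of freedom must exceed 2 for the normal approximation ",
         "(variance d/(d-2) undefined)")
  }
  ifelse(is.finite(df), df / (df - 2), 1)
}

# derive a reproducible 32-bit sub-seed from a base seed and indices
.sub_seed <- function(seed, ...) {
  idx <- c(...)
  mult <- c(7919, 104729, 15485863)[seq_along(idx)]
  as.integer((as.numeric(seed) + sum(as.numeric(idx) * mult)) %% 2147483587)
}

.stopifnot_prob <- function(x, name, open0 = TRUE, open1 = TRUE) {
  bad <- !is.finite(x) | (if (open0) x <= 0 else x < 0) | (if (open1) x >= 1 else x > 1)
  if (any(bad)) {
    stop(sprintf("`%s` must lie in %s0, 1%s", name,
                 if (open0) "(" else "[", if (open1) ")" else "]"))
  }
  invisible(x)
}
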