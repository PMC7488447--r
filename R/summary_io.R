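#' Describe one study's summary statistics
#'
#' @param study_id Label for the study.
#' @param mode `"t"` (effect sizes + standard errors) or `"p"` (P values).
#' @param theta1 Marginal non-null proportion for the study.  Defaults to
#'   1e-3 for omics QTL studies and 1e-5 for GWAS when `type` is given.
#' @param n Sample size (required in t-mode).
#' @param df Residual degrees of freedom of the summary statistics
#'   (t-mode; default `n - 2`).
#' @param type `"qtl"` or `"gwas"`, used only to pick the default `theta1`.
#' @return Object of class `study_spec`.
#' @export
study_spec <- function(study_id, mode = c("t", "p"), theta1 = NULL,
                       n = NULL, df = NULL, type = c("qtl", "gwas")) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  if (is.null(theta1)) theta1 <- if (type == "gwas") 1e-5 else 1e-3
  .stopifnot_prob(theta1, "theta1")
  if (mode == "t") {
    if (is.null(n) || n <= 0) stop("t-mode requires a positive sample size `n`")
    if (is.null(df)) df <- n - 2
    if (df != round(df) || df <= 0) stop("`df` must be a positive integer")
  } else if (!is.null(df)) {
    stop("`df` applies to t-mode only")
  }
  structure(list(study_id = study_id, mode = mode, theta1 = theta1,
                 n = n, df = df, type = type),
            class = "study_spec")
}

#' Read and validate a per-study summary-statistic table
#'
#' Reads a tab-delimited file with a header.  A t-mode study needs columns
#' `snp_id`, `beta`, `se`, `maf` (an explicit per-SNP weight column `w` may
#' replace `maf`); a P-mode study needs `snp_id`, `p`.  Rows violating the
#' invariants (`se > 0`, `maf` in (0, 0.5], `p` in (0, 1], numeric cells)
#' are reported with their file line numbers and the read fails, so silent
#' truncation of a study cannot occur.
#'
#' @param path Path to the TSV file.
#' @param spec A [study_spec()] describing the study.
#' @return A validated `data.frame` (class `summary_table`) with the spec
#'   attached as attribute `"spec"`.
#' @export
read_summary_table <- function(path, spec) {
  stopifnot(inherits(spec, "study_spec"))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = TRUE)
  need <- if (spec$mode == "t") {
    if ("w" %in% names(raw)) c("snp_id", "beta", "se", "w") else c("snp_id", "beta", "se", "maf")
  } else c("snp_id", "p")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- raw[, intersect(c(need, "n", "df"), names(raw)), drop = FALSE]
  lines <- seq_len(nrow(out)) + 1L # header occupies line 1
  for (col in setdiff(names(out), "snp_id")) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    bad <- is.na(val) & !(out[[col]] %in% c("NA", ""))
    if (any(bad)) {
      stop(sprintf("non-numeric value in column '%s' at line(s) %s", col,
                   paste(utils::head(lines[bad], 5L), collapse = ", ")))
    }
    out[[col]] <- val
  }
  fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad) > 0L) {
      stop(sprintf("%s at line(s) %s", what,
                   paste(utils::head(lines[bad], 5L), collapse = ", ")))
    }
  }
  if (spec$mode == "t") {
    fail(!is.finite(out$beta), "missing or non-finite beta")
    fail(!is.finite(out$se) | out$se <= 0, "standard error must be > 0")
    if ("maf" %in% names(out)) {
      fail(!is.finite(out$maf) | out$maf <= 0 | out$maf > 0.5,
           "MAF must lie in (0, 0.5]")
    } else {
      fail(!is.finite(out$w) | out$w <= 0, "weight must be > 0")
    }
  } else {
    fail(!is.finite(out$p) | out$p <= 0 | out$p > 1, "P value must lie in (0, 1]")
  }
  if (anyDuplicated(out$snp_id)) {
    stop("duplicated snp_id: ", out$snp_id[anyDuplicated(out$snp_id)])
  }
  attr(out, "spec") <- spec
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Align studies on shared SNPs
#'
#' Inner-joins the tables on `snp_id`, preserving the SNP order of the
#' first study, and reports how many SNPs each study loses.  SNP matching
#' is by exact string identifier; effect alleles must be pre-harmonized by
#' the caller (no strand flipping or allele matching is attempted, since a
#' silent flip would corrupt the sign of every downstream statistic).
#'
#' @param tables List of two or more [read_summary_table()] results (or
#'   data frames with an `snp_id` column).
#' @return List with `snp_id` (the shared SNPs, in study-1 order),
#'   `tables` (the aligned tables), and `n_dropped` per study.
#' @export
align_studies <- function(tables) {
  if (length(tables) < 2L) stop("need at least two studies to align")
  ids <- lapply(tables, function(tb) tb$snp_id)
  shared <- ids[[1L]]
  for (k in 2L:length(tables)) shared <- shared[shared %in% ids[[k]]]
  if (length(shared) == 0L) stop("no SNP is shared by all studies")
  aligned <- lapply(tables, function(tb) tb[match(shared, tb$snp_id), , drop = FALSE])
  n_dropped <- vapply(ids, function(x) length(x) - length(shared), integer(1))
  message(sprintf("aligned %d SNPs; dropped per study: %s",
                  length(shared), paste(n_dropped, collapse = ", ")))
  list(snp_id = shared, tables = aligned, n_dropped = n_dropped)
}

#' Fit the pattern mixture from per-study summary tables
#'
#' High-level wrapper: aligns the tables on shared SNPs, runs the per-study
#' preprocessing (moderated t-statistics in t-mode), and fits [patmix()].
#' All studies must use the same mode.
#'
#' @param tables List of [read_summary_table()] results.
#' @param specs List of matching [study_spec()] objects.
#' @param ... Passed on to [patmix()].
#' @return A fitted `patmix` object carrying the shared `snp_id`s.
#' @export
patmix_tables <- function(tables, specs, ...) {
  stopifnot(length(tables) == length(specs))
  modes <- vapply(specs, `[[`, character(1), "mode")
  if (length(unique(modes)) != 1L) stop("all studies must share one mode")
  al <- align_studies(tables)
  m <- length(al$snp_id); J <- length(tables)
  theta1 <- vapply(specs, `[[`, numeric(1), "theta1")
  if (modes[1L] == "t") {
    X <- matrix(0, m, J); W <- matrix(1, m, J); dfs <- numeric(J)
    for (j in seq_len(J)) {
      tb <- al$tables[[j]]; sp <- specs[[j]]
      n_j <- if (!is.null(tb$n)) tb$n else sp$n
      d1 <- if (!is.null(tb$df)) tb$df[1L] else sp$df
      if ("maf" %in% names(tb)) {
        mod <- moderate_tstats(tb$beta, tb$se, tb$maf, n_j, d1)
      } else {
        s_sq <- tb$se^2 / tb$w
        prior <- fit_variance_prior(s_sq, d1)
        mod <- list(t_mod = moderated_t(tb$beta, s_sq, tb$w, prior$d0,
                                        prior$s0_sq, d1),
                    w = tb$w, d_total = prior$d0 + d1)
      }
      X[, j] <- mod$t_mod; W[, j] <- mod$w; dfs[j] <- mod$d_total
    }
    patmix(X, theta1 = theta1, mode = "t", df = dfs, weights = W,
           snp_id = al$snp_id, ...)
  } else {
    P <- vapply(al$tables, function(tb) tb$p, numeric(m))
    patmix(P, theta1 = theta1, mode = "p", snp_id = al$snp_id, ...)
  }
}

#' Write per-SNP posterior probabilities to a TSV file
#'
#' One row per SNP: identifier, posterior probability of each pattern
#' (columns labeled by the binary pattern string), and the most probable
#' pattern.  Values are written at full double precision so a read-back
#' reproduces them exactly.
#'
#' @param fit A fitted [patmix()] model.
#' @param path Output file path.
#' @return The path, invisibly.
#' @seealso [read_patmix_results()]
#' @export
write_patmix_results <- function(fit, path) {
  ids <- if (!is.null(fit$snp_id)) fit$snp_id else paste0("snp_", seq_len(fit$m))
  df <- data.frame(snp_id = ids, check.names = FALSE)
  for (k in seq_len(fit$K)) df[[fit$labels[k]]] <- fit$post[, k]
  df$top_pattern <- fit$labels[fit$a_hat]
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a posterior table written by [write_patmix_results()]
#'
#' @param path File path.
#' @return Data frame with the SNP identifiers, one numeric column per
#'   pattern, and the `top_pattern` label.
#' @export
read_patmix_results <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  for (col in setdiff(names(df), c("snp_id", "top_pattern"))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
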