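write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

t_spec <- function(...) study_spec("s1", mode = "t", n = 500, ...)

test_that("well-formed tables round-trip and invariants reject with line numbers", {
  df <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                   beta = c(0.1, -0.2, 0.05),
                   se = c(0.02, 0.05, 0.01),
                   maf = c(0.3, 0.11, 0.5))
  tb <- read_summary_table(write_tsv(df), t_spec())
  expect_s3_class(tb, "summary_table")
  expect_equal(nrow(tb), 3L)
  expect_equal(tb$beta, df$beta)

  # se = 0 on data row 2 -> reported as file line 3 (header is line 1)
  bad <- df; bad$se[2] <- 0
  expect_error(read_summary_table(write_tsv(bad), t_spec()), "line\\(s\\) 3")

  # non-numeric cell located precisely
  bad2 <- df; bad2$maf <- as.character(bad2$maf); bad2$maf[3] <- "x"
  expect_error(read_summary_table(write_tsv(bad2), t_spec()), "line\\(s\\) 4")

  # P-mode boundary: p = 1 is legal, p = 0 is not
  pdf <- data.frame(snp_id = c("rs1", "rs2"), p = c(1, 0.05))
  ptab <- read_summary_table(write_tsv(pdf), study_spec("s", mode = "p"))
  expect_equal(ptab$p, c(1, 0.05))
  pdf$p[2] <- 0
  expect_error(read_summary_table(write_tsv(pdf), study_spec("s", mode = "p")),
               "0, 1")

  # schema errors name the missing columns
  expect_error(read_summary_table(write_tsv(df[, 1:2]), t_spec()), "se")
  expect_error(read_summary_table(
    write_tsv(data.frame(snp_id = c("a", "a"), p = c(.1, .2))),
    study_spec("s", mode = "p")), "duplicated")
})

test_that("alignment inner-joins on shared SNPs in first-study order", {
  t1 <- data.frame(snp_id = paste0("rs", 1:8), p = runif(8))
  t2 <- data.frame(snp_id = paste0("rs", c(10, 5, 3, 2, 1, 9)), p = runif(6))
  al <- suppressMessages(align_studies(list(t1, t2)))
  expect_equal(al$snp_id, paste0("rs", c(1, 2, 3, 5)))
  expect_equal(al$tables[[2]]$snp_id, al$snp_id)
  expect_equal(al$n_dropped, c(4L, 2L))

  # identical tables: nothing dropped
  al2 <- suppressMessages(align_studies(list(t1, t1)))
  expect_equal(al2$snp_id, t1$snp_id)
  expect_equal(al2$n_dropped, c(0L, 0L))

  # order-insensitivity of the shared set
  al3 <- suppressMessages(align_studies(list(t1[sample(8), ], t2[sample(6), ])))
  expect_setequal(al3$snp_id, al$snp_id)

  # disjoint SNP sets cannot be analyzed jointly
  t3 <- data.frame(snp_id = paste0("rs", 100:105), p = runif(6))
  expect_error(suppressMessages(align_studies(list(t1, t3))), "shared")
})

test_that("results tables round-trip at full precision", {
  fx <- small_fit(m = 2000, seed = 60)
  path <- tempfile(fileext = ".tsv")
  write_patmix_results(fx$fit, path)
  back <- read_patmix_results(path)
  expect_equal(nrow(back), fx$fit$m)
  for (k in seq_len(fx$fit$K)) {
    expect_equal(back[[fx$fit$labels[k]]], unname(fx$fit$post[, k]),
                 tolerance = 1e-15)
  }
  expect_equal(back$top_pattern, unname(fx$fit$labels[fx$fit$a_hat]))
})

test_that("table-level fitting reproduces the matrix-level fit", {
  set.seed(61)
  m <- 3000; n <- 800
  ids <- paste0("rs", seq_len(m))
  tabs <- lapply(1:2, function(j) {
    maf <- runif(m, 0.05, 0.5)
    se <- sqrt(1 / (2 * n * maf * (1 - maf))) # unit residual variance
    assoc <- seq_len(50) + (j - 1) * 25       # partially shared signals
    beta <- rnorm(m, 0, se * 0.2)
    beta[assoc] <- rnorm(50, 0, se[assoc] * 8)
    data.frame(snp_id = ids, beta = beta, se = se, maf = maf)
  })
  paths <- vapply(tabs, write_tsv, character(1))
  specs <- list(study_spec("a", "t", theta1 = 0.02, n = n),
                study_spec("b", "t", theta1 = 0.02, n = n))
  tables <- Map(read_summary_table, paths, specs)
  fit <- suppressMessages(patmix_tables(tables, specs))
  expect_s3_class(fit, "patmix")
  expect_equal(fit$m, m)
  expect_equal(fit$snp_id, ids)

  # equivalent hand-built pipeline
  mods <- lapply(tabs, function(tb) moderate_tstats(tb$beta, tb$se, tb$maf, n))
  fit2 <- patmix(cbind(mods[[1]]$t_mod, mods[[2]]$t_mod),
                 theta1 = 0.02, df = c(mods[[1]]$d_total, mods[[2]]$d_total),
                 weights = cbind(mods[[1]]$w, mods[[2]]$w))
  expect_equal(fit$pi, fit2$pi, tolerance = 1e-12)
  expect_equal(fit$post, fit2$post, tolerance = 1e-12)
})

test_that("study specs default theta1 by study type and validate df", {
  expect_equal(study_spec("x", "t", n = 100)$theta1, 1e-3)
  expect_equal(study_spec("x", "t", n = 100, type = "gwas")$theta1, 1e-5)
  expect_error(study_spec("x", "t"), "sample size")
  expect_error(study_spec("x", "p", df = 10), "t-mode only")
  expect_error(study_spec("x", "t", n = 100, theta1 = 1.5), "0, 1")
})
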