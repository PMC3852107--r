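test_that("read_expression_tsv is header-driven and validates cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tr1_t0\tr1_t6\tr1_t24\tr1_t120\tr2_t0\tr2_t6\tr2_t24\tr2_t120",
               "g1\t1\t2\t3\t4\t5\t6\t7\t8",
               "g2\t10\t20\t30\t40\t50\t60\t70\t80"), path)
  se <- read_expression_tsv(path)
  expect_equal(dim(se), c(2L, 8L))
  expect_equal(timepoints(se), c(0, 6, 24, 120))
  tc <- timecourse(se, "g1")
  expect_equal(dim(tc), c(2L, 4L))
  expect_equal(unname(tc["r2", "t120"]), 8)

  # shuffled column order gives the identical object
  shuf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tr2_t120\tr1_t6\tr2_t0\tr1_t0\tr1_t120\tr2_t6\tr2_t24\tr1_t24",
               "g1\t8\t2\t5\t1\t4\t6\t7\t3",
               "g2\t80\t20\t50\t10\t40\t60\t70\t30"), shuf)
  expect_equal(SummarizedExperiment::assay(read_expression_tsv(shuf)),
               SummarizedExperiment::assay(se))

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tr1_t0\tr1_t6\tr2_t0\tr2_t6",
               "g1\t1\t-2\t3\t4"), neg)
  expect_error(read_expression_tsv(neg), "negative intensity for gene g1")

  miss <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tr1_t0\tr1_t6\tr2_t0\tr2_t6",
               "g1\t1\t\t3\t4"), miss)
  expect_error(read_expression_tsv(miss), "missing value for gene g1")

  badhdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\trep1.time0\tr1_t6\tr2_t0\tr2_t6",
               "g1\t1\t2\t3\t4"), badhdr)
  expect_error(read_expression_tsv(badhdr), "unrecognised expression column")
})

test_that("kendall_tau matches hand-enumerated examples", {
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  # 6 pairs: 5 concordant, 1 discordant
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  expect_error(kendall_tau(1, 1:2), "unequal")
  expect_error(kendall_tau(numeric(1), numeric(1)), "length >= 2")
  expect_true(is.na(kendall_tau(c(1, 1, 1), c(1, 2, 3))))
})

test_that("kendall_tau equals the brute-force all-pairs oracle", {
  set.seed(7)
  for (i in 1:250) {
    n <- sample(2:8, 1)
    x <- sample(0:5, n, replace = TRUE)  # ties likely
    y <- sample(0:5, n, replace = TRUE)
    expect_equal(kendall_tau(x, y), brute_kendall(x, y),
                 info = paste(c("x:", x, "y:", y), collapse = " "))
  }
})

test_that("kendall_tau is symmetric and rank-invariant", {
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(kendall_tau(x, y), kendall_tau(y, x))
    expect_equal(kendall_tau(exp(x), y), kendall_tau(x, y))
    expect_equal(kendall_tau(x, 3 * y + 10), kendall_tau(x, y))
  }
})

test_that("fold_change is direction-symmetric on replicate means", {
  expect_equal(fold_change(tc2(c(100, 1, 1, 150), c(100, 1, 1, 150))), 1.5)
  expect_equal(fold_change(tc2(c(200, 1, 1, 100), c(200, 1, 1, 100))), 2.0)
  expect_equal(fold_change(tc2(rep(100, 4), rep(100, 4))), 1.0)
  expect_error(fold_change(tc2(c(0, 1, 1, 1), c(0, 1, 1, 1))), "zero endpoint")
})

test_that("the DE rule reproduces the worked verdicts", {
  cfg <- analysis_config()
  # concordant on {0,24,120} h; FC = 159/100
  r <- is_differentially_expressed(
    tc2(c(100, 150, 155, 160), c(100, 160, 140, 158)), cfg)
  expect_true(r$de)
  expect_equal(r$fold_change, 1.59)
  expect_true(list(c(1L, 3L, 4L)) %in% r$qualifying_subsets)

  # flat: concordance irrelevant, FC 1.0 < 1.5
  r <- is_differentially_expressed(
    tc2(c(100, 100, 100, 100), c(100, 100, 100, 100)), cfg)
  expect_false(r$de)
  expect_equal(r$fold_change, 1.0)

  # anti-concordant replicates: every 3-subset tau = -1
  r <- is_differentially_expressed(
    tc2(c(100, 150, 155, 160), c(160, 120, 110, 100)), cfg)
  expect_false(r$concordant)
  expect_false(r$de)
  expect_equal(length(r$qualifying_subsets), 0L)
})

test_that("raising thresholds never grows the DE set", {
  set.seed(21)
  tcs <- replicate(60, matrix(100 * exp(rnorm(8, 0, 0.4)), 2, 4),
                   simplify = FALSE)
  de_at <- function(tau, fc) {
    cfg <- analysis_config(tau_threshold = tau, fc_threshold = fc)
    vapply(tcs, function(tc) is_differentially_expressed(tc, cfg)$de,
           logical(1))
  }
  base <- de_at(0.6, 1.5)
  expect_true(all(de_at(0.9, 1.5) <= base))
  expect_true(all(de_at(0.6, 2.5) <= base))
  expect_true(all(de_at(0.3, 1.2) >= base))
})

test_that("correlate_pair signs follow the tau cutoff", {
  cfg <- analysis_config()
  up <- tc2(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(correlate_pair(up, tc2(c(10, 20, 30, 40), c(10, 20, 30, 40)),
                              cfg)$sign, "+")
  dn <- tc2(c(4, 3, 2, 1), c(4, 3, 2, 1))
  r <- correlate_pair(up, dn, cfg)
  expect_equal(r$sign, "-")
  expect_equal(r$tau, -1)
  # 4 concordant, 2 discordant pairs: tau = 1/3 -> none
  weak <- tc2(c(2, 1, 4, 3), c(2, 1, 4, 3))
  r <- correlate_pair(up, weak, cfg)
  expect_equal(r$sign, "none")
  expect_equal(r$tau, 1 / 3)
})

test_that("on 4 untied points the admissible |tau| at cutoff 0.6 is {2/3, 1}", {
  perms <- matrix(unlist(combinat_perms <- list(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))),
    ncol = 4, byrow = TRUE)
  taus <- apply(perms, 1, function(p) kendall_tau(1:4, p))
  expect_setequal(round(unique(taus), 10),
                  round(c(-1, -2/3, -1/3, 0, 1/3, 2/3, 1), 10))
  admissible <- taus[abs(taus) >= 0.6]
  expect_setequal(round(unique(abs(admissible)), 10), round(c(2/3, 1), 10))
})
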