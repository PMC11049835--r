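test_that("exact Mann-Whitney matches the worked examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_true(r$exact)
  expect_equal(r$p_two_sided, 0.1)

  r <- mann_whitney_u(c(1, 4), c(2, 3))
  expect_equal(r$u, 2)
  expect_equal(r$p_two_sided, 1)

  r <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$p_two_sided, 1)
})

test_that("the exact path equals brute-force enumeration on small samples", {
  set.seed(100)
  for (i in 1:40) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    vals <- sample(1:1000, nx + ny)  # distinct values, no ties
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    r <- mann_whitney_u(x, y)
    expect_true(r$exact)
    expect_equal(r$p_two_sided, brute_mw_p(x, y))
  }
})

test_that("U identity and invariance under monotone transforms hold", {
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1)); y <- rnorm(sample(3:40, 1))
    rxy <- mann_whitney_u(x, y); ryx <- mann_whitney_u(y, x)
    n1 <- length(x); n2 <- length(y)
    ux <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
    expect_equal(ux + (n1 * n2 - ux), n1 * n2)
    expect_equal(rxy$u, ryx$u)  # min convention is symmetric
    t1 <- mann_whitney_u(exp(x), exp(y))
    expect_equal(rxy$p_two_sided, t1$p_two_sided)
  }
})

test_that("the approximate path agrees with wilcox.test with ties and correction", {
  set.seed(102)
  for (i in 1:15) {
    x <- sample(1:8, 20, replace = TRUE)
    y <- sample(3:10, 25, replace = TRUE)
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_false(ours$exact)
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
  # and the exact path against wilcox.test's exact p when there are no ties
  set.seed(103)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mann_whitney_u(x, y)$p_two_sided,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("summaries report medians and percentile ranges of the cells", {
  s <- summarize_metric(1:5)
  expect_equal(s$median, 3)
  s <- summarize_metric(rep(2.2, 10))
  expect_equal(diff(s$interval), 0)
  set.seed(104)
  draws <- sample_preset(test_presets()$low_score, 10000)
  expect_equal(summarize_metric(draws$cta)$median, 0.349, tolerance = 0.01)
})

test_that("compare_groups assembles the comparison and validates classes", {
  meas <- data.frame(class = rep(c("low", "high"), each = 30),
                     itd = c(rnorm(30, 0.38, 0.05), rnorm(30, 0.27, 0.05)),
                     cta = c(rnorm(30, 0.35, 0.04), rnorm(30, 0.20, 0.04)),
                     qc_pass = TRUE)
  cmp <- compare_groups(meas, "cta")
  expect_s3_class(cmp, "group_comparison")
  expect_equal(cmp$n_low, 30)
  expect_lt(cmp$p_two_sided, 1e-5)
  expect_true(cmp$u_statistic >= 0 && cmp$u_statistic <= 30 * 30)
  expect_lt(cmp$interval_low[1], cmp$median_low)
  # identical groups: no separation
  same <- data.frame(class = rep(c("low", "high"), each = 20),
                     itd = rep(seq(0.1, 0.5, length.out = 20), 2),
                     qc_pass = TRUE)
  expect_gt(compare_groups(same, "itd")$p_two_sided, 0.9)
  one <- meas[meas$class == "low", ]
  expect_error(compare_groups(one, "itd"), "both classes")
  # QC-failed cells are excluded
  meas2 <- meas
  meas2$qc_pass[meas2$class == "high"] <- FALSE
  expect_error(compare_groups(meas2, "itd"), "both classes")
})
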