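test_that("EdU fraction arithmetic and contracts", {
  expect_equal(edu_fraction(10, 40), 0.25)
  expect_equal(edu_fraction(0, 40), 0)
  expect_equal(edu_fraction(40, 40), 1)
  expect_error(edu_fraction(5, 0), "n_total")
  expect_error(edu_fraction(41, 40), "n_positive")
})

test_that("2^-ddCt matches hand calculation and normalizes the calibrator", {
  # calibrator samples engineered to mean dCt = 3; test sample dCt = 4
  ct <- rbind(
    data.frame(sample_id = "c1", group = "ctrl", gene = "Cdh2", ct = 22.5),
    data.frame(sample_id = "c1", group = "ctrl", gene = "Rpl19", ct = 20),
    data.frame(sample_id = "c2", group = "ctrl", gene = "Cdh2", ct = 23.5),
    data.frame(sample_id = "c2", group = "ctrl", gene = "Rpl19", ct = 20),
    data.frame(sample_id = "A", group = "trt", gene = "Cdh2", ct = 24),
    data.frame(sample_id = "A", group = "trt", gene = "Rpl19", ct = 20))
  res <- ddct_fold_change(ct, calibrator_group = "ctrl")
  a <- res[res$sample_id == "A", ]
  expect_equal(a$delta_ct, 4)
  expect_equal(a$ddct, 1)       # 4 - mean(2.5, 3.5)
  expect_equal(a$fold_change, 0.5)

  # ddct = 0 -> fold 1 (a calibrator sample at the calibrator mean)
  expect_equal(res$fold_change[res$ddct == 0], numeric(0))  # none exactly 0 here
  # geometric mean of calibrator folds is 1 per gene
  cal <- res[res$group == "ctrl", ]
  expect_equal(exp(mean(log(cal$fold_change))), 1, tolerance = 1e-12)

  # missing reference gene for a sample
  bad <- ct[ct$sample_id != "A" | ct$gene != "Rpl19", ]
  expect_error(ddct_fold_change(bad, calibrator_group = "ctrl"), "reference")
})

test_that("percent change follows the reduction-positive convention exactly", {
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "non-zero")
  # exact identity: percent_change(a, a(1-e)) = 100 e
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, -50, 50); if (a == 0) a <- 1
    e <- runif(1, -1, 1)
    expect_equal(percent_change(a, a * (1 - e)), 100 * e, tolerance = 1e-12)
  }
  # an increase comes out negative
  expect_lt(percent_change(1.61, 2.40), 0)
})

test_that("group summaries report mean and SEM, with NA at n = 1", {
  s <- summarize_group(c(2, 4), "pair")
  expect_equal(s$mean, 3)
  expect_equal(s$sem, 1)  # sd = sqrt(2), sem = sqrt(2)/sqrt(2)
  expect_true(is.na(summarize_group(5)$sem))
  expect_equal(summarize_group(rep(7, 4))$sem, 0)
  expect_error(summarize_group(numeric(0)), "empty")
})

test_that("t-tests match direct-formula oracles on fixed vectors", {
  # one-sample: t = (xbar - mu0) / (s / sqrt(n))
  x <- c(0.5, 0.6, 0.4, 0.5)
  t_hand <- (mean(x) - 1) / (sd(x) / sqrt(4))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  r <- t_test_report(x, mu0 = 1)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(r$p, p_hand, tolerance = 1e-12)
  expect_identical(r$test, "one_sample")

  # two-sample pooled-variance Student
  a <- c(3.1, 2.7, 3.5, 3.0, 2.9)
  b <- c(2.2, 2.6, 2.1, 2.8)
  sp2 <- ((5 - 1) * var(a) + (4 - 1) * var(b)) / (5 + 4 - 2)
  t_hand2 <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  p_hand2 <- 2 * pt(-abs(t_hand2), df = 7)
  r2 <- t_test_report(a, b)
  expect_equal(r2$t, t_hand2, tolerance = 1e-12)
  expect_equal(r2$df, 7)
  expect_equal(r2$p, p_hand2, tolerance = 1e-12)

  # Welch variant: df from the Welch-Satterthwaite formula
  r3 <- t_test_report(a, b, variant = "welch")
  se2 <- var(a) / 5 + var(b) / 4
  df_w <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
  expect_equal(r3$df, df_w, tolerance = 1e-12)

  # degenerate inputs
  expect_equal(t_test_report(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_equal(t_test_report(c(1, 1, 1), c(1, 1, 1))$t, 0)
  r4 <- t_test_report(c(2, 2, 2), mu0 = 2)
  expect_equal(r4$p, 1)
  expect_error(t_test_report(1), "n >= 2")
  expect_error(t_test_report(c(1, 2)), "mu0")
})

test_that("percent change in the report uses the reference group mean", {
  a <- c(10, 12, 11); b <- c(7, 8, 9)
  r <- t_test_report(a, b)
  expect_equal(r$percent_change, 100 * (mean(a) - mean(b)) / mean(a))
  r1 <- t_test_report(c(0.5, 0.6, 0.4), mu0 = 1)
  expect_equal(r1$percent_change, 100 * (1 - 0.5))
})
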