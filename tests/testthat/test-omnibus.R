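test_that("one-way table matches the published single-factor analysis", {
  fit <- fit_incubation()
  tab <- fit$table
  expect_equal(round(tab$SS, 4), 0.1104)
  expect_equal(round(tab$MS, 4), 0.0368)
  expect_equal(round(fit$MSe, 4), 0.0105)
  expect_equal(round(tab$F, 4), 3.5124)
  expect_equal(round(tab$p.value, 4), 0.0145)
  expect_equal(tab$g, tab$df * tab$F)
  expect_equal(tab$MS, tab$SS / tab$df)
})

test_that("identical cells give a zero statistic and p = 1", {
  fit <- suppressMessages(anopa_oneway(c(5, 5), c(20, 20)))
  expect_equal(fit$table$SS, 0)
  expect_equal(fit$table$F, 0)
  expect_equal(fit$table$p.value, 1)
})

test_that("two-group analysis equals the brute-force known-variance form", {
  # hand computation: F = (A1 - A2)^2 / 2 / MSe with p = 2
  a <- anscombe_transform(c(1, 9), c(10, 10))
  mse <- mean(theoretical_variance(c(10, 10)))
  fit <- suppressMessages(anopa_oneway(c(1, 9), c(10, 10)))
  expect_equal(fit$table$F, (a[1] - a[2])^2 / 2 / mse, tolerance = 1e-12)
})

test_that("one-way with p = 2 is the squared two-sample z on A scores", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:80, 2, replace = TRUE)
    s <- rbinom(2, n, runif(2, 0.1, 0.9))
    fit <- suppressMessages(anopa_oneway(s, n))
    a <- anscombe_transform(s, n)
    # F = MS/MSe = ((a1-a2)^2/2) / ((v1+v2)/2), so g = (a1-a2)^2/(v1+v2):
    # the squared z of a two-sample test with known variances
    z2 <- (a[1] - a[2])^2 / sum(theoretical_variance(n))
    expect_equal(fit$table$g, z2, tolerance = 1e-12)
  }
})

test_that("two-way table matches the published factorial analysis", {
  fit <- fit_graduation()
  tab <- fit$table
  expect_equal(round(tab$SS, 4), c(0.0017, 0.0445, 0.0149))
  expect_equal(round(tab$MS, 4), c(0.0017, 0.0222, 0.0074))
  expect_equal(round(fit$MSe, 4), 0.0035)
  expect_equal(round(tab$F, 4), c(0.5010, 6.3948, 2.1400))
  expect_equal(round(tab$p.value[2], 4), 0.0017)
  expect_equal(round(tab$p.value[3], 4), 0.1177)
})

test_that("two-way sums of squares decompose the between-cell total", {
  fit <- fit_graduation()
  expect_equal(sum(fit$table$SS), fit$SS_between, tolerance = 1e-10)
  expect_equal(round(fit$SS_between, 4), 0.0611)
  # all-equal grid: every SS vanishes
  flat <- suppressMessages(anopa_twoway(rep(6, 4), rep(20, 4),
                                        rep(c("a", "b"), 2),
                                        rep(c("x", "y"), each = 2)))
  expect_equal(flat$table$SS, rep(0, 3))
})

test_that("2x2 interaction SS equals the closed-form contrast", {
  set.seed(7)
  s <- rbinom(4, 30, c(0.3, 0.5, 0.6, 0.4))
  fit <- suppressMessages(anopa_twoway(s, rep(30, 4),
                                       rep(c("a", "b"), each = 2),
                                       rep(c("x", "y"), 2)))
  a <- anscombe_transform(s, rep(30, 4))  # order a:x, a:y, b:x, b:y
  expect_equal(fit$table$SS[3], (a[1] - a[2] - a[3] + a[4])^2 / 4,
               tolerance = 1e-12)
})

test_that("results are invariant to cell and level relabeling", {
  perm <- c(3, 1, 4, 2)
  f1 <- fit_incubation()
  f2 <- suppressMessages(anopa_oneway(incubation$s[perm], incubation$n[perm],
                                      labels = incubation$group[perm]))
  expect_equal(f2$table[c("SS", "MS", "F", "p.value")],
               f1$table[c("SS", "MS", "F", "p.value")])
  g1 <- fit_graduation()
  gp <- c(2, 1, 6, 5, 4, 3)
  g2 <- suppressMessages(anopa_twoway(
    graduation$s[gp], graduation$n[gp],
    graduation$moment[gp], graduation$ses[gp]))
  expect_equal(sort(g2$table$SS), sort(g1$table$SS), tolerance = 1e-12)
})

test_that("chi-square form agrees with the F form at huge denominator df", {
  for (g in c(0.3, 3, 10.5372, 25)) {
    for (df in c(1, 2, 3, 6)) {
      expect_equal(pvalue_from_g(g, df),
                   pf(g / df, df, 1e9, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  }
  expect_equal(pvalue_from_g(0, 3), 1)
  # df = 2 closed form: exp(-g/2)
  expect_equal(pvalue_from_g(12.7898, 2), exp(-12.7898 / 2), tolerance = 1e-12)
})

test_that("Williams correction matches the published values and limits", {
  expect_equal(williams_correction(3, 4, 97), 1.0086, tolerance = 1e-4)
  expect_equal(williams_correction(3, 4, 1e9), 1, tolerance = 1e-7)
  expect_true(williams_correction(2, 6, 50) > 1)
  expect_error(williams_correction(0, 4, 97))
  expect_error(williams_correction(3, 1, 97))
})

test_that("corrected p-values are never smaller than uncorrected", {
  set.seed(99)
  for (i in 1:25) {
    p <- sample(2:5, 1)
    n <- sample(5:40, p, replace = TRUE)
    s <- rbinom(p, n, runif(p, 0.1, 0.9))
    fit <- suppressMessages(anopa_oneway(s, n))
    expect_gte(fit$table$p.corrected, fit$table$p.value)
    expect_lte(fit$table$F.corrected, fit$table$F)
  }
})

test_that("repeated-measures table matches the published drug study", {
  fit <- anopa_within_counts(delirium_counts, delirium_n, delirium_alpha1)
  expect_equal(round(fit$table$SS, 4), 0.0534)
  expect_equal(round(fit$table$MS, 4), 0.0178)
  expect_equal(round(fit$MSe, 4), 0.0058)
  expect_equal(fit$table$F, 3.043, tolerance = 0.01)
  # correction for k = 4 cells over N = 120 observations
  expect_equal(fit$table$correction, 1 + 15 / (6 * 120 * 3))
})

test_that("alpha1 = 0 reduces the within error term to the between one", {
  fit <- anopa_within_counts(c(5, 9), 20, alpha1 = 0)
  expect_equal(fit$MSe, theoretical_variance(20))
})

test_that("two-measurement within analysis equals the dependent z-squared", {
  fit <- anopa_within_counts(c(5, 12), 25, alpha1 = 0.3)
  a <- anscombe_transform(c(5, 12), c(25, 25))
  z2 <- (a[1] - a[2])^2 / 2 / ((1 - 0.3) / (4 * 25.5))
  # g = 1 * F; F = var(a)/MSe = ((a1-a2)^2/2)/MSe
  expect_equal(fit$table$g, z2, tolerance = 1e-12)
})

test_that("within analysis rejects degenerate or out-of-range alpha1", {
  expect_error(anopa_within_counts(c(5, 9), 20, alpha1 = 1), "degenerate")
  expect_warning(anopa_within_counts(c(5, 9), 20, alpha1 = -0.2), "inflates")
})

test_that("formula interface routes every design correctly", {
  f1 <- suppressMessages(anopa(cbind(s, n) ~ group, incubation))
  expect_equal(f1$table$F, 3.5124, tolerance = 1e-4)
  f2 <- suppressMessages(anopa(cbind(s, n) ~ moment * ses, graduation))
  expect_equal(f2$table$F[2], 6.3949, tolerance = 1e-3)
  # raw long between data aggregate to the same fit
  raw <- data.frame(
    group = rep(incubation$group, incubation$n),
    y = unlist(mapply(function(s, n) c(rep(1, s), rep(0, n - s)),
                      incubation$s, incubation$n)))
  f3 <- suppressMessages(anopa(y ~ group, raw))
  expect_equal(f3$table$F, f1$table$F, tolerance = 1e-12)
  expect_equal(f3$cells$s[order(f3$cells$label)],
               incubation$s[order(incubation$group)])
  # wide binary matrix routes to the within analysis
  set.seed(5)
  m <- matrix(rbinom(120, 1, 0.4), 30, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  d <- as.data.frame(m)
  f4 <- suppressWarnings(anopa(cbind(t1, t2, t3, t4) ~ 1, d))
  expect_equal(f4$design, "within")
  expect_equal(f4$alpha1, consistency_stats(m)$alpha1)
  expect_equal(f4$cells$s, unname(colSums(m)))
})

test_that("invalid designs are rejected with informative errors", {
  expect_error(anopa_oneway(5, 20), "at least 2")
  expect_error(anopa_twoway(c(1, 2, 3), c(10, 10, 10),
                            c("a", "a", "b"), c("x", "y", "x")),
               "complete")
  expect_error(suppressMessages(anopa(y ~ g, data.frame(y = c(0, 1, 2),
                                                        g = c("a", "b", "a")))),
               "0/1")
})

test_that("a total sample below the sufficient size triggers the advisory", {
  msgs <- testthat::capture_messages(anopa_oneway(c(2, 8), c(10, 10)))
  expect_true(any(grepl("conservative", msgs)))
  msgs <- testthat::capture_messages(anopa_oneway(c(10, 5), c(30, 10)))
  expect_true(any(grepl("ratio", msgs)))
})
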