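test_that("standalone interval applies the known standard error", {
  ci <- anopa_ci(14, 22, gamma = 0.95)
  expect_equal(ci$SE, 0.5 / sqrt(22.5), tolerance = 1e-12)
  a <- anscombe_transform(14, 22)
  z <- qnorm(0.975)
  expect_equal(ci$A.lower, a - z * ci$SE, tolerance = 1e-12)
  expect_equal(ci$A.upper, a + z * ci$SE, tolerance = 1e-12)
})

test_that("difference-adjusted limits match the published proportions", {
  # Sudoku cell: printed interval [0.34, 0.90]
  ci <- anopa_ci(14, 22, adjust = "difference")
  expect_lt(abs(ci$p.lower - 0.34), 0.005)
  expect_gte(ci$p.upper, 0.87)
  expect_lte(ci$p.upper, 0.90)
  # Breath cell: 0.64 must fall outside, upper limit about 0.43
  ci2 <- anopa_ci(5, 27, adjust = "difference")
  expect_lt(abs(ci2$p.upper - 0.43), 0.005)
  expect_lt(ci2$p.upper, 0.64)
})

test_that("difference adjustment widens A-scale width by exactly sqrt(2)", {
  base <- anopa_ci(10, 30)
  diff <- anopa_ci(10, 30, adjust = "difference")
  expect_equal((diff$A.upper - diff$A.lower) / (base$A.upper - base$A.lower),
               sqrt(2), tolerance = 1e-12)
})

test_that("correlation adjustment interpolates between the other two", {
  # alpha1 = 1/2 recovers the standalone width; alpha1 = 0 the difference
  base <- anopa_ci(8, 30)
  half <- anopa_ci(8, 30, adjust = "correlation", alpha1 = 0.5)
  zero <- anopa_ci(8, 30, adjust = "correlation", alpha1 = 0)
  diff <- anopa_ci(8, 30, adjust = "difference")
  expect_equal(half$A.lower, base$A.lower, tolerance = 1e-12)
  expect_equal(half$A.upper, base$A.upper, tolerance = 1e-12)
  expect_equal(zero$A.lower, diff$A.lower, tolerance = 1e-12)
  # drug-study cells at the estimated correlation: direct formula check
  ci <- anopa_ci(delirium_counts, rep(30, 4), adjust = "correlation",
                 alpha1 = delirium_alpha1)
  hw <- sqrt(2 * (1 - delirium_alpha1)) * qnorm(0.975) * 0.5 / sqrt(30.5)
  expect_equal(ci$A.upper - ci$A, rep(hw, 4), tolerance = 1e-12)
})

test_that("interval widths shrink with n and with alpha1", {
  w <- sapply(c(10, 30, 100, 500), function(n)
    with(anopa_ci(round(n / 3), n), A.upper - A.lower))
  expect_true(all(diff(w) < 0))
  w2 <- sapply(c(0, 0.3, 0.6, 0.9), function(a1)
    with(anopa_ci(10, 30, adjust = "correlation", alpha1 = a1),
         A.upper - A.lower))
  expect_true(all(diff(w2) < 0))
})

test_that("proportion-scale limits stay ordered and inside the unit range", {
  for (n in c(1, 2, 5, 20, 75, 200)) {
    s <- 0:n
    ci <- anopa_ci(s, rep(n, length(s)), adjust = "difference")
    expect_true(all(ci$p.lower >= 0 & ci$p.upper <= 1))
    expect_true(all(ci$p.lower <= ci$p & ci$p <= ci$p.upper))
    expect_true(all(ci$A.lower >= 0 & ci$A.upper <= pi / 2))
  }
})

test_that("interval width collapses as gamma tends to zero", {
  ci <- anopa_ci(10, 30, gamma = 1e-9)
  expect_equal(ci$A.upper - ci$A.lower, 0, tolerance = 1e-9)
})

test_that("interval inputs are validated", {
  expect_error(anopa_ci(10, 30, gamma = 1.2), "gamma")
  expect_error(anopa_ci(10, 30, adjust = "correlation"), "alpha1")
  expect_error(anopa_ci(10, 30, adjust = "correlation", alpha1 = 1),
               "degenerate")
})

test_that("confint method picks the design-appropriate adjustment", {
  fit <- fit_incubation()
  ci <- confint(fit)
  expect_equal(unique(ci$adjust), "difference")
  wfit <- anopa_within_counts(delirium_counts, 30, delirium_alpha1)
  wci <- confint(wfit)
  expect_equal(unique(wci$adjust), "correlation")
  expect_equal(wci$A, unname(coef(wfit)))
})
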