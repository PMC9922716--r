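test_that("HSD finds the single published pairwise difference", {
  fit <- fit_incubation()
  hsd <- TukeyHSD(fit)
  expect_equal(hsd$q[1], 4.524, tolerance = 1e-2)
  expect_identical(sort(c(hsd$cell1[1], hsd$cell2[1])),
                   c("Breath", "Sudoku"))
  expect_lt(hsd$p.value[1], 0.01)
  expect_true(all(hsd$p.value[-1] > 0.05))
  # sorted by decreasing q, corrected q never exceeds q
  expect_true(all(diff(hsd$q) <= 0))
  expect_true(all(hsd$q.corrected <= hsd$q))
  expect_true(all(hsd$p.corrected >= hsd$p.value))
})

test_that("identical cells give q = 0 and p = 1", {
  hsd <- tukey_hsd(c(0.6, 0.6), MSe = 0.01)
  expect_equal(hsd$q, 0)
  expect_equal(hsd$p.value, 1)
})

test_that("with two means the range statistic is z * sqrt(2)", {
  a <- anscombe_transform(c(6, 14), c(20, 20))
  v <- theoretical_variance(20)
  hsd <- tukey_hsd(a, MSe = v, n_means = 2)
  z <- abs(a[1] - a[2]) / sqrt(2 * v)
  expect_equal(hsd$q, z * sqrt(2), tolerance = 1e-12)
  expect_equal(hsd$p.value, 2 * pnorm(z, lower.tail = FALSE),
               tolerance = 1e-5)
})

test_that("HSD p-values decrease monotonically in q", {
  p <- stats::ptukey(seq(0.5, 6, by = 0.5), 4, 1e6, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("HSD validates the error term", {
  expect_error(tukey_hsd(c(0.4, 0.6), MSe = 0), "MSe")
  expect_error(tukey_hsd(0.4, MSe = 0.1), "at least 2")
})

test_that("contrast machinery reduces to the two-group z test", {
  a <- anscombe_transform(c(6, 14), c(20, 25))
  v <- theoretical_variance(c(20, 25))
  lc <- linear_contrast(a, v, c(1, -1))
  z <- (a[1] - a[2]) / sqrt(sum(v))
  expect_equal(lc$z, z, tolerance = 1e-12)
  expect_equal(lc$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("equal scores give a null contrast; sign flips leave p alone", {
  lc <- linear_contrast(rep(0.7, 4), rep(0.01, 4), c(1, -1, 2, -2))
  expect_equal(lc$z, 0)
  expect_equal(lc$p.value, 1)
  a <- anscombe_transform(c(10, 14, 7, 5), c(30, 22, 18, 27))
  v <- theoretical_variance(c(30, 22, 18, 27))
  w <- c(-1, 3, -1, -1)
  l1 <- linear_contrast(a, v, w)
  l2 <- linear_contrast(a, v, -w)
  expect_equal(l1$estimate, sum(w * a), tolerance = 1e-12)
  expect_equal(l2$estimate, -l1$estimate)
  expect_equal(abs(l2$z), abs(l1$z))
  expect_equal(l2$p.value, l1$p.value)
})

test_that("a full orthogonal contrast set reconstitutes the omnibus g", {
  # equal n so the cells share one variance and orthogonality is exact
  s <- c(9, 15, 6, 12); n <- rep(25, 4)
  fit <- suppressMessages(anopa_oneway(s, n))
  a <- anscombe_transform(s, n)
  v <- theoretical_variance(n)
  W <- list(c(1, -1, 0, 0), c(1, 1, -2, 0), c(1, 1, 1, -3))
  z2 <- sum(vapply(W, function(w) linear_contrast(a, v, w)$z^2, numeric(1)))
  expect_equal(z2, fit$table$g, tolerance = 1e-6)
})

test_that("contrasts reject weights that do not sum to zero", {
  expect_error(linear_contrast(c(0.4, 0.6), c(0.01, 0.01), c(1, 1)),
               "sum to zero")
  expect_error(linear_contrast(c(0.4, 0.6), c(0.01, 0.01), c(1, -1, 0)),
               "equal length")
})

test_that("fitted-object wrappers agree with the low-level functions", {
  fit <- fit_incubation()
  lc1 <- anopa_contrast(fit, c(1, -1, 0, 0))
  lc2 <- linear_contrast(fit$cells$A, fit$cells$var_th, c(1, -1, 0, 0))
  expect_equal(lc1, lc2)
})
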