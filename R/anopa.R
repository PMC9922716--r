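#' Analysis of proportions on Anscombe-transformed scores
#'
#' Fits an ANOVA-analogue model to proportions. Cell counts are mapped to
#' the arcsine scale with [anscombe_transform()], where the error variance
#' is known theoretically, so effects are tested against a chi-square
#' reference with infinite error degrees of freedom: the statistic
#' \eqn{g = \mathrm{df} \times F} is a central chi-square on the effect's
#' degrees of freedom under the null.
#'
#' Three designs are supported, chosen from the formula:
#' \describe{
#'   \item{one-way between}{`cbind(s, n) ~ group` with one row per cell
#'     (aggregate counts), or `y ~ group` with one 0/1 row per
#'     observation.}
#'   \item{two-way between}{`cbind(s, n) ~ f1 * f2` (or `y ~ f1 * f2`),
#'     complete crossed design.}
#'   \item{one-way within}{`cbind(m1, m2, ..., mk) ~ 1` where the k
#'     left-hand columns are the repeated binary measurements, one row
#'     per participant.}
#' }
#'
#' For between designs the error term is the mean of the cellwise
#' theoretical variances (option `mse = "harmonic"` uses the
#' harmonic-mean shortcut \eqn{1/(4(\tilde n + 1/2))}). For within
#' designs the error term is deflated by the unitary inter-measure
#' correlation \eqn{\alpha_1} (see [consistency_stats()]):
#' \eqn{\mathrm{MS}_e = (1 - \alpha_1)/(4(n + 1/2))}.
#'
#' Williams' correction divides each statistic by
#' \eqn{c = 1 + (m^2 - 1)/(6 N \mathrm{df})} (with `m` cells involved in
#' the effect and `N` the total observation count), guarding against the
#' mild chi-square excess in moderate samples; see [williams_correction()].
#'
#' @param formula model formula as described above.
#' @param data a data frame holding the formula's variables.
#' @param correction logical; apply Williams' correction (default `TRUE`).
#' @param alpha decision threshold used for the advisory messages
#'   (default 0.05).
#' @param mse `"exact"` (mean of cellwise theoretical variances, default)
#'   or `"harmonic"`.
#' @param variance_divisor divisor used for the within-design consistency
#'   statistics, `"n-1"` (default) or `"n"`; see [consistency_stats()].
#' @return An object of class `"anopa"`: a list with the design label,
#'   the cell table (labels, `s`, `n`, proportion, `A`, `var_th`), the
#'   test table (`SS`, `df`, `MS`, `F`, `g`, `p.value`, and corrected
#'   columns), `MSe`, the total count `N`, and for within designs the
#'   [consistency_stats()] result.
#' @examples
#' incubation <- data.frame(
#'   group = c("Crossword", "Sudoku", "Chant", "Breath"),
#'   s = c(10, 14, 7, 5), n = c(30, 22, 18, 27)
#' )
#' fit <- anopa(cbind(s, n) ~ group, incubation)
#' fit
#' summary(fit)
#' @seealso [anopa_oneway()], [anopa_twoway()], [anopa_within()] for the
#'   direct count interfaces; [TukeyHSD.anopa()], [confint.anopa()].
#' @export
anopa <- function(formula, data, correction = TRUE, alpha = 0.05,
                  mse = c("exact", "harmonic"),
                  variance_divisor = c("n-1", "n")) {
  mse <- match.arg(mse)
  variance_divisor <- match.arg(variance_divisor)
  if (!inherits(formula, "formula")) stop("'formula' must be a formula", call. = FALSE)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  rhs <- attr(stats::terms(formula), "term.labels")
  fac <- mf[, setdiff(names(mf), colnames(y)), drop = FALSE]
  fac <- fac[, !vapply(fac, function(v) is.matrix(v), logical(1)), drop = FALSE]

  if (is.matrix(y) && length(rhs) == 0) {
    # within-subject wide layout: k binary columns
    fit <- anopa_within(y, correction = correction, alpha = alpha,
                        variance_divisor = variance_divisor)
  } else if (is.matrix(y) && ncol(y) == 2) {
    # aggregate counts: first column s, second n
    fit <- fit_between(y[, 1], y[, 2], fac, rhs, correction, alpha, mse)
  } else if (!is.matrix(y)) {
    if (!all(y %in% c(0, 1))) {
      stop("raw outcomes must be coded 0/1", call. = FALSE)
    }
    agg <- aggregate_binary(y, fac, rhs)
    fit <- fit_between(agg$s, agg$n, agg$fac, rhs, correction, alpha, mse)
  } else {
    stop("unrecognized design: left-hand side must be cbind(s, n), ",
         "a 0/1 outcome, or a matrix of repeated binary measurements",
         call. = FALSE)
  }
  fit$call <- match.call()
  fit
}

aggregate_binary <- function(y, fac, rhs) {
  rhs <- intersect(rhs, names(fac))   # drop interaction terms like f1:f2
  if (length(rhs) < 1 || length(rhs) > 2) {
    stop("raw between-subject data need 1 or 2 factor terms", call. = FALSE)
  }
  if (length(rhs) == 1) {
    lev <- unique_levels(fac[[rhs]])
    f <- factor(fac[[rhs]], levels = lev)
    grid <- data.frame(lev, stringsAsFactors = FALSE)
  } else {
    l1 <- unique_levels(fac[[rhs[1]]])
    l2 <- unique_levels(fac[[rhs[2]]])
    f <- interaction(factor(fac[[rhs[1]]], levels = l1),
                     factor(fac[[rhs[2]]], levels = l2), lex.order = TRUE)
    grid <- data.frame(rep(l1, each = length(l2)), rep(l2, length(l1)),
                       stringsAsFactors = FALSE)
  }
  names(grid) <- rhs
  s <- as.vector(tapply(y, f, sum))
  n <- as.vector(tapply(y, f, length))
  if (anyNA(n)) stop("incomplete factorial design: empty cells", call. = FALSE)
  list(s = s, n = n, fac = grid)
}

unique_levels <- function(v) if (is.factor(v)) levels(droplevels(v)) else unique(v)

fit_between <- function(s, n, fac, rhs, correction, alpha, mse) {
  if (length(rhs) == 1) {
    anopa_oneway(s, n, labels = as.character(fac[[rhs]]),
                 factor_name = rhs, correction = correction,
                 alpha = alpha, mse = mse)
  } else if (length(rhs) >= 2) {
    f1 <- as.character(fac[[rhs[1]]])
    f2 <- as.character(fac[[rhs[2]]])
    anopa_twoway(s, n, f1, f2, factor_names = rhs[1:2],
                 correction = correction, alpha = alpha, mse = mse)
  } else {
    stop("between-subject designs need at least one factor", call. = FALSE)
  }
}

#' One-way between-subject analysis from cell counts
#'
#' @param s,n vectors of successes and cell sizes, one entry per group.
#' @param labels optional group labels.
#' @param factor_name name used for the effect row.
#' @inheritParams anopa
#' @return An `"anopa"` object; see [anopa()].
#' @examples
#' anopa_oneway(c(10, 14, 7, 5), c(30, 22, 18, 27))
#' @export
anopa_oneway <- function(s, n, labels = NULL, factor_name = "P",
                         correction = TRUE, alpha = 0.05,
                         mse = c("exact", "harmonic")) {
  mse <- match.arg(mse)
  check_counts(s, n)
  p <- length(s)
  if (p < 2) stop("a one-way design needs at least 2 cells", call. = FALSE)
  if (length(n) != p) stop("'s' and 'n' must have equal length", call. = FALSE)
  if (is.null(labels)) labels <- paste0("cell", seq_len(p))

  A <- anscombe_transform(s, n)
  MSe <- if (mse == "exact") mean(theoretical_variance(n)) else
    theoretical_variance(harmonic_mean(n))
  MS <- stats::var(A)
  SS <- (p - 1) * MS
  N <- sum(n)
  c_w <- williams_correction(df_effect = p - 1, n_cells = p, N = N)
  tab <- effect_table(factor_name, SS, p - 1, MSe, c_w, correction)

  out <- structure(list(
    design = "oneway", factor_names = factor_name,
    cells = data.frame(label = labels, s = s, n = n, p = s / n, A = A,
                       var_th = theoretical_variance(n),
                       stringsAsFactors = FALSE),
    table = tab, MSe = MSe, N = N, n_means = p,
    correction = correction, alpha = alpha,
    call = sys.call()), class = "anopa")
  advise(out)
  out
}

#' Two-way between-subject analysis from cell counts
#'
#' Effects are decomposed from unweighted marginal means of the cell
#' scores (each cell counts once regardless of its size); the interaction
#' sum of squares is obtained by subtraction from the between-cell total.
#'
#' @param s,n vectors of successes and sizes, one entry per cell of the
#'   complete `p x q` grid.
#' @param f1,f2 factor level labels of each cell (first and second
#'   factor).
#' @param factor_names length-2 character, names for the effect rows.
#' @inheritParams anopa
#' @return An `"anopa"` object; see [anopa()].
#' @examples
#' anopa_twoway(c(75, 84, 62, 52, 40, 42), c(89, 92, 77, 72, 52, 63),
#'              f1 = rep(c("early", "late"), 3),
#'              f2 = rep(c("low", "mid", "high"), each = 2))
#' @export
anopa_twoway <- function(s, n, f1, f2, factor_names = c("P", "Q"),
                         correction = TRUE, alpha = 0.05,
                         mse = c("exact", "harmonic")) {
  mse <- match.arg(mse)
  check_counts(s, n)
  f1 <- as.character(f1); f2 <- as.character(f2)
  l1 <- unique(f1); l2 <- unique(f2)
  p <- length(l1); q <- length(l2)
  if (p < 2 || q < 2) stop("both factors need at least 2 levels", call. = FALSE)
  if (length(s) != p * q || anyDuplicated(paste(f1, f2))) {
    stop("cells must form a complete p x q grid with no duplicates", call. = FALSE)
  }
  miss <- setdiff(paste(rep(l1, each = q), rep(l2, p)), paste(f1, f2))
  if (length(miss)) {
    stop("incomplete factorial design; missing cells: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  A <- anscombe_transform(s, n)
  Am <- matrix(NA_real_, p, q, dimnames = list(l1, l2))
  Am[cbind(match(f1, l1), match(f2, l2))] <- A
  gm <- mean(Am)
  SSB <- sum((Am - gm)^2)
  SSP <- q * sum((rowMeans(Am) - gm)^2)
  SSQ <- p * sum((colMeans(Am) - gm)^2)
  SSPQ <- SSB - SSP - SSQ
  MSe <- if (mse == "exact") mean(theoretical_variance(n)) else
    theoretical_variance(harmonic_mean(n))
  N <- sum(n)

  cP <- williams_correction(p - 1, p, N)
  cQ <- williams_correction(q - 1, q, N)
  cPQ <- williams_correction((p - 1) * (q - 1), p * q, N)
  tab <- rbind(
    effect_table(factor_names[1], SSP, p - 1, MSe, cP, correction),
    effect_table(factor_names[2], SSQ, q - 1, MSe, cQ, correction),
    effect_table(paste(factor_names, collapse = ":"), SSPQ,
                 (p - 1) * (q - 1), MSe, cPQ, correction))

  out <- structure(list(
    design = "twoway", factor_names = factor_names,
    cells = data.frame(label = paste(f1, f2, sep = ":"),
                       f1 = f1, f2 = f2, s = s, n = n, p = s / n, A = A,
                       var_th = theoretical_variance(n),
                       stringsAsFactors = FALSE),
    A_matrix = Am, SS_between = SSB,
    table = tab, MSe = MSe, N = N, n_means = p * q,
    correction = correction, alpha = alpha,
    call = sys.call()), class = "anopa")
  advise(out)
  out
}

#' One-way repeated-measures analysis from a binary matrix
#'
#' Each column of `x` is one measurement occasion, each row one
#' participant; entries are 0/1. Column totals give the cell counts. The
#' error term is the theoretical variance deflated by the unitary
#' inter-measure correlation \eqn{\alpha_1}:
#' \eqn{\mathrm{MS}_e = (1 - \alpha_1) / (4(n + 1/2))}.
#'
#' @param x an `n x k` matrix (or data frame) of 0/1 values, `k >= 2`.
#' @inheritParams anopa
#' @return An `"anopa"` object with a `consistency` element; see
#'   [anopa()] and [consistency_stats()].
#' @export
anopa_within <- function(x, correction = TRUE, alpha = 0.05,
                         variance_divisor = c("n-1", "n")) {
  variance_divisor <- match.arg(variance_divisor)
  x <- as.matrix(x)
  cs <- consistency_stats(x, variance_divisor)   # validates the matrix
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("m", seq_len(ncol(x)))
  fit <- anopa_within_counts(colSums(x), nrow(x), alpha1 = cs$alpha1,
                             labels = labels, correction = correction,
                             alpha = alpha)
  fit$consistency <- cs
  fit$call <- sys.call()
  fit
}

#' Repeated-measures analysis from column counts and a known correlation
#'
#' The repeated-measures table only needs the per-measurement success
#' counts, the common `n` and the unitary correlation \eqn{\alpha_1}, so
#' published aggregate results can be re-analyzed without the raw 0/1
#' matrix. With raw data, use [anopa_within()], which estimates
#' \eqn{\alpha_1} itself.
#'
#' @param s vector of per-measurement success counts (length `k >= 2`).
#' @param n common number of participants.
#' @param alpha1 unitary inter-measure correlation, `< 1`; negative
#'   values are retained (they inflate the error term) with a warning.
#' @param labels optional measurement labels.
#' @param factor_name name used for the effect row.
#' @inheritParams anopa
#' @return An `"anopa"` object; see [anopa()].
#' @examples
#' anopa_within_counts(c(15, 6, 8, 10), 30, alpha1 = 0.2881)
#' @export
anopa_within_counts <- function(s, n, alpha1, labels = NULL,
                                correction = TRUE, alpha = 0.05,
                                factor_name = "P") {
  if (length(n) != 1) stop("'n' must be a single common size", call. = FALSE)
  check_counts(s, rep(n, length(s)))
  k <- length(s)
  if (k < 2) stop("a within design needs at least 2 measurements", call. = FALSE)
  if (!is.finite(alpha1) || alpha1 >= 1) {
    stop("degenerate data: 'alpha1' must be < 1", call. = FALSE)
  }
  if (alpha1 < 0) {
    warning("negative alpha1 (", signif(alpha1, 4),
            ") inflates the error term", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("m", seq_len(k))

  A <- anscombe_transform(s, rep(n, k))
  MSe <- (1 - alpha1) / (4 * (n + 0.5))
  N <- n * k
  c_w <- williams_correction(df_effect = k - 1, n_cells = k, N = N)
  tab <- effect_table(factor_name, (k - 1) * stats::var(A), k - 1, MSe,
                      c_w, correction)

  out <- structure(list(
    design = "within", factor_names = factor_name,
    cells = data.frame(label = labels, s = s, n = n, p = s / n, A = A,
                       var_th = theoretical_variance(rep(n, k)),
                       stringsAsFactors = FALSE),
    table = tab, MSe = MSe, N = N, n_means = k, alpha1 = alpha1,
    correction = correction, alpha = alpha,
    call = sys.call()), class = "anopa")
  advise(out)
  out
}

# one row of the test table
effect_table <- function(effect, SS, df, MSe, c_w, correction) {
  MS <- SS / df
  Fv <- MS / MSe
  g <- df * Fv
  data.frame(
    effect = effect, SS = SS, df = df, MS = MS, F = Fv, g = g,
    p.value = pvalue_from_g(g, df),
    correction = c_w,
    F.corrected = if (correction) Fv / c_w else NA_real_,
    p.corrected = if (correction) pvalue_from_g(g / c_w, df) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Williams' small-sample correction factor
#'
#' \eqn{c = 1 + (m^2 - 1) / (6 N \, \mathrm{df})}, where `m` is the
#' number of cells involved in the effect, `df` the effect's degrees of
#' freedom and `N` the total number of observations. The test statistic
#' (F or g) is divided by `c`, which is `>= 1` and tends to 1 as `N`
#' grows; Tukey HSD statistics are divided by `sqrt(c)`.
#'
#' @param df_effect effect degrees of freedom, `>= 1`.
#' @param n_cells number of cells involved, `>= 2`.
#' @param N total observation count, `>= 1`.
#' @return The correction factor, a scalar `>= 1`.
#' @examples
#' williams_correction(3, 4, 97)   # 1.0086
#' @export
williams_correction <- function(df_effect, n_cells, N) {
  if (!is.finite(df_effect) || df_effect < 1) stop("'df_effect' must be >= 1", call. = FALSE)
  if (!is.finite(n_cells) || n_cells < 2) stop("'n_cells' must be >= 2", call. = FALSE)
  if (!is.finite(N) || N < 1) stop("'N' must be >= 1", call. = FALSE)
  1 + (n_cells^2 - 1) / (6 * N * df_effect)
}

#' P-value of the chi-square form of the test
#'
#' With the error variance known, \eqn{g = \mathrm{df} \times F} is a
#' central chi-square variate on the effect's degrees of freedom under
#' the null; this is the `F(df, Inf)` upper tail without any
#' infinite-df special-casing.
#'
#' @param g non-negative statistic.
#' @param df effect degrees of freedom.
#' @return Upper-tail probability in `(0, 1]`.
#' @examples
#' pvalue_from_g(3 * 3.5124, 3)   # 0.0145
#' @export
pvalue_from_g <- function(g, df) {
  if (any(!is.finite(g)) || any(g < 0)) stop("'g' must be >= 0", call. = FALSE)
  stats::pchisq(g, df, lower.tail = FALSE)
}

# advisory messages: sufficient sample size and group balance
advise <- function(fit) {
  cells <- fit$cells
  if (fit$design != "within") {
    pe <- cells$p[which.max(abs(cells$p - 0.5))]
    pe <- min(max(pe, 1e-6), 1 - 1e-6)
    need <- sufficient_n(nrow(cells), pe)
    if (fit$N < need) {
      message("total n = ", fit$N, " is below the sufficient sample size ",
              need, "; the test will be conservative")
    }
    if (max(cells$n) / min(cells$n) > 1.5) {
      message("largest/smallest group size ratio exceeds 1.5; ",
              "calibration may degrade")
    }
  }
  invisible(fit)
}
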