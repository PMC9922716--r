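#' Observed standardized effect size
#'
#' \eqn{f^2 = \mathrm{MS_P} / (\tilde n \, \mathrm{MS}_e)}, the effect
#' variance per observation over the error variance, with \eqn{\tilde n}
#' the harmonic mean group size; \eqn{\eta^2 = f^2/(1+f^2)} is the
#' corresponding proportion of variance.
#'
#' @param object an `"anopa"` fit, or the `MS_P` value directly.
#' @param MSe,n_tilde error mean square and harmonic mean group size;
#'   taken from the fit when `object` is one.
#' @return A list with `f2`, `eta2`, `sigma2_P` (= MS_P), `sigma2_e`
#'   (= `n_tilde * MSe`).
#' @examples
#' fit <- anopa_oneway(c(10, 14, 7, 5), c(30, 22, 18, 27))
#' observed_effect_size(fit)   # f2 = 0.1505
#' @export
observed_effect_size <- function(object, MSe = NULL, n_tilde = NULL) {
  if (inherits(object, "anopa")) {
    MS_P <- object$table$MS[1]
    MSe <- object$MSe
    n_tilde <- harmonic_mean(object$cells$n)
  } else {
    MS_P <- object
  }
  if (is.null(MSe) || is.null(n_tilde)) {
    stop("supply 'MSe' and 'n_tilde' when not passing a fit", call. = FALSE)
  }
  if (MSe <= 0 || n_tilde <= 0 || MS_P < 0) {
    stop("inputs must be positive ('MS_P' may be zero)", call. = FALSE)
  }
  f2 <- MS_P / (n_tilde * MSe)
  list(f2 = f2, eta2 = f2 / (1 + f2), sigma2_P = MS_P,
       sigma2_e = n_tilde * MSe)
}

#' Planning effect size from expected proportions
#'
#' Converts a set of expected cell proportions into the population
#' effect size \eqn{f^2 = 4 \frac{p-1}{p} \mathrm{var}(A_i)}: the
#' population variance of the transformed scores (divisor `p`, hence the
#' \eqn{(p-1)/p} factor on the sample variance) over the size-free error
#' variance \eqn{1/4}. With a planned per-group `n`, the proportions are
#' first converted to counts `s = round(prop * n)` and transformed with
#' the full offset form; without `n`, the size-free
#' \eqn{\arcsin\sqrt{\pi}} is used.
#'
#' @param props expected proportions per cell, each in `(0, 1)`.
#' @param n_per_group planned per-group size, or `NULL` for the
#'   size-free variant.
#' @return The effect size `f2` (a scalar).
#' @examples
#' planning_f2(c(0.32, 0.64, 0.40, 0.16), 25)   # 0.1281
#' planning_f2(c(0.32, 0.64, 0.40, 0.16))       # 0.1372, size-free
#' @export
planning_f2 <- function(props, n_per_group = NULL) {
  if (length(props) < 2) stop("need at least 2 proportions", call. = FALSE)
  if (any(props <= 0) || any(props >= 1)) {
    stop("proportions must be strictly inside (0, 1)", call. = FALSE)
  }
  p <- length(props)
  if (is.null(n_per_group)) {
    A <- asin(sqrt(props))
  } else {
    if (n_per_group < 1) stop("'n_per_group' must be >= 1", call. = FALSE)
    s <- round(props * n_per_group)
    if (any(abs(props * n_per_group - s) > 0.01)) {
      warning("expected counts prop * n are not whole; rounded to nearest",
              call. = FALSE)
    }
    A <- anscombe_transform(s, rep(n_per_group, p))
  }
  4 * ((p - 1) / p) * stats::var(A)
}

#' Noncentrality parameter for a planned total sample
#'
#' @param n_total planned total sample size.
#' @param f2 effect size (see [planning_f2()]).
#' @return \eqn{\lambda = n_{total} f^2}.
#' @examples
#' noncentrality(100, 0.1281)   # 12.81
#' @export
noncentrality <- function(n_total, f2) {
  if (n_total <= 0 || f2 < 0) stop("inputs must be positive", call. = FALSE)
  n_total * f2
}

#' Power of the chi-square-form omnibus test
#'
#' Probability that a noncentral chi-square on `df_effect` degrees of
#' freedom with noncentrality `lambda` exceeds the central critical
#' value at level `alpha` — the power of the test actually performed
#' (error degrees of freedom infinite).
#'
#' @param lambda noncentrality, `>= 0`.
#' @param df_effect effect degrees of freedom.
#' @param alpha decision threshold.
#' @return Power in `(0, 1)`.
#' @examples
#' power_from_lambda(12.8076, 3)   # 0.8653
#' @export
power_from_lambda <- function(lambda, df_effect, alpha = 0.05) {
  if (any(lambda < 0)) stop("'lambda' must be >= 0", call. = FALSE)
  crit <- stats::qchisq(1 - alpha, df_effect)
  stats::pchisq(crit, df_effect, ncp = lambda, lower.tail = FALSE)
}

#' Total sample size required for a target power
#'
#' Finds the smallest total `N`, rounded up to a multiple of the number
#' of groups `p` (equal group sizes), whose power at effect size `f2`
#' reaches the target. The default reference distribution is the
#' noncentral F with denominator degrees of freedom `N - p` — the
#' convention of standard ANOVA power software, which reproduces
#' published planning numbers; `denominator = "chisq"` uses the
#' chi-square (infinite-df) form matching the omnibus test itself and
#' yields slightly smaller sizes.
#'
#' @param f2 effect size, `> 0` (see [planning_f2()]).
#' @param p number of groups.
#' @param alpha decision threshold.
#' @param power target power in `(alpha, 1)`.
#' @param denominator `"fdist"` (default) or `"chisq"`.
#' @return A list with `n_total` (multiple of `p`), `n_per_group`, and
#'   `n_exact` (the unrounded solution).
#' @examples
#' f2 <- planning_f2(c(0.32, 0.64, 0.40, 0.16), 25)
#' required_n(f2, p = 4)           # 92 (exact 89.13)
#' required_n(f2, p = 4, denominator = "chisq")$n_total  # 88
#' @export
required_n <- function(f2, p, alpha = 0.05, power = 0.80,
                       denominator = c("fdist", "chisq")) {
  denominator <- match.arg(denominator)
  if (!is.finite(f2) || f2 <= 0) {
    stop("no solution: 'f2' must be > 0", call. = FALSE)
  }
  if (power <= alpha || power >= 1) {
    stop("'power' must lie in (alpha, 1)", call. = FALSE)
  }
  pw <- function(N) {
    if (denominator == "chisq") {
      power_from_lambda(N * f2, p - 1, alpha)
    } else {
      df2 <- N - p
      if (df2 < 1) return(0)
      stats::pf(stats::qf(1 - alpha, p - 1, df2), p - 1, df2,
                ncp = N * f2, lower.tail = FALSE)
    }
  }
  hi <- p + 1
  while (pw(hi) < power && hi < 1e7) hi <- hi * 2
  n_exact <- stats::uniroot(function(N) pw(N) - power,
                            lower = p + 1, upper = hi, tol = 1e-6)$root
  n_per <- ceiling(n_exact / p)
  list(n_total = p * n_per, n_per_group = n_per, n_exact = n_exact)
}

#' Sufficient total sample size for a calibrated test
#'
#' Rule of thumb for the total sample at which the sampling variance of
#' transformed scores matches the theoretical variance, so that the test
#' holds its nominal level:
#' \eqn{\lceil 20 p + 50\,|\arcsin(p_{extreme}) - \arcsin(0.5)| \rceil},
#' with the arcsine applied to the proportion itself. Roughly 20
#' observations per group, plus a surcharge as the most extreme
#' proportion moves away from one half.
#'
#' @param p_cells number of groups (cells).
#' @param p_extreme most extreme expected/observed proportion, in
#'   `(0, 1)`.
#' @return An integer total sample size.
#' @examples
#' sufficient_n(4, 0.19)   # 97
#' sufficient_n(4, 0.16)   # 99
#' @export
sufficient_n <- function(p_cells, p_extreme) {
  if (p_cells < 1) stop("'p_cells' must be >= 1", call. = FALSE)
  if (p_extreme <= 0 || p_extreme >= 1) {
    stop("'p_extreme' must be inside (0, 1)", call. = FALSE)
  }
  as.integer(ceiling(20 * p_cells + 50 * abs(asin(p_extreme) - asin(0.5))))
}
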