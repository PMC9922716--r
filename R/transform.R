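#' Anscombe arcsine transform of a binomial count
#'
#' Maps a count of successes `s` out of `n` observations to
#' \eqn{A = \arcsin\sqrt{(s + 3/8)/(n + 3/4)}}, in radians. The offsets
#' 3/8 and 3/4 keep the score strictly inside \eqn{(0, \pi/2)} even at
#' `s = 0` or `s = n`, and give the score the proportion-free asymptotic
#' variance \eqn{1/(4(n + 1/2))} (see [theoretical_variance()]), which is
#' what makes ANOVA-style tests with a known error term possible.
#'
#' @param s integer vector of success counts, `0 <= s <= n`.
#' @param n integer vector of cell sizes, `n >= 1`. Recycled against `s`.
#' @return Numeric vector of transformed scores in radians.
#' @examples
#' anscombe_transform(10, 30)            # 0.6198
#' anscombe_transform(c(10, 14), c(30, 22))
#' @seealso [back_transform()] for the inverse, [theoretical_variance()].
#' @export
anscombe_transform <- function(s, n) {
  check_counts(s, n)
  asin(sqrt((s + 3 / 8) / (n + 3 / 4)))
}

#' Theoretical variance of an Anscombe-transformed score
#'
#' The asymptotic variance of the transformed score depends only on the
#' cell size: \eqn{\mathrm{var_{th}} = 1/(4(n + 1/2))} radians squared,
#' whatever the underlying success probability. Because this error
#' variance is not estimated from data, tests built on it have infinite
#' error degrees of freedom.
#'
#' @param n integer vector of cell sizes, `n >= 1`.
#' @return Numeric vector of variances (radians squared).
#' @examples
#' theoretical_variance(30)   # 1/122
#' @export
theoretical_variance <- function(n) {
  if (length(n) == 0 || any(!is.finite(n)) || any(n < 1)) {
    stop("'n' must contain only finite values >= 1", call. = FALSE)
  }
  1 / (4 * (n + 0.5))
}

#' Harmonic mean of group sizes
#'
#' @param sizes numeric vector of positive group sizes.
#' @return The harmonic mean `length(sizes) / sum(1/sizes)`.
#' @examples
#' harmonic_mean(c(30, 22, 18, 27))  # 23.3399
#' @export
harmonic_mean <- function(sizes) {
  if (length(sizes) == 0) stop("'sizes' must be non-empty", call. = FALSE)
  if (any(!is.finite(sizes)) || any(sizes < 1)) {
    stop("'sizes' must contain only finite values >= 1", call. = FALSE)
  }
  length(sizes) / sum(1 / sizes)
}

#' Map a transformed score back to the proportion scale
#'
#' Inverts the arcsine transform. The `"naive"` mode applies
#' \eqn{\sin^2(A)}; the `"precise"` mode undoes the 3/8 and 3/4 offsets,
#' \eqn{((n + 3/4)\sin^2(A) - 3/8)/n}, and is the exact inverse of
#' [anscombe_transform()]. Inputs are clamped to \eqn{[0, \pi/2]} first
#' and precise results are clamped to \eqn{[0, 1]}: confidence limits can
#' step outside the admissible range for small `n`.
#'
#' @param A numeric vector of transformed scores (radians).
#' @param n cell size(s); required for `mode = "precise"`.
#' @param mode `"precise"` (default) or `"naive"`.
#' @return Numeric vector of proportions in `[0, 1]`.
#' @examples
#' back_transform(anscombe_transform(10, 30), 30)  # 1/3, round trip
#' back_transform(pi / 4, mode = "naive")          # 0.5
#' @export
back_transform <- function(A, n = NULL, mode = c("precise", "naive")) {
  mode <- match.arg(mode)
  if (any(!is.finite(A))) stop("'A' must be finite", call. = FALSE)
  A <- pmin(pmax(A, 0), pi / 2)
  if (mode == "naive") return(sin(A)^2)
  if (is.null(n)) {
    stop("precise back-transform requires 'n'", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("'n' must contain only finite values >= 1", call. = FALSE)
  }
  pmin(pmax(((n + 3 / 4) * sin(A)^2 - 3 / 8) / n, 0), 1)
}

# shared validation for (s, n) count pairs
check_counts <- function(s, n) {
  if (length(s) == 0 || length(n) == 0) {
    stop("'s' and 'n' must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(s))) stop("'s' must be finite", call. = FALSE)
  if (any(!is.finite(n))) stop("'n' must be finite", call. = FALSE)
  if (any(abs(s - round(s)) > 1e-8)) {
    stop("'s' must contain whole numbers", call. = FALSE)
  }
  if (any(abs(n - round(n)) > 1e-8)) {
    stop("'n' must contain whole numbers", call. = FALSE)
  }
  if (any(n < 1)) stop("'n' must be >= 1", call. = FALSE)
  if (any(s < 0)) stop("'s' must be >= 0", call. = FALSE)
  if (any(s > n)) stop("'s' must not exceed 'n'", call. = FALSE)
  invisible(TRUE)
}
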