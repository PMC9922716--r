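#' Internal consistency of repeated binary measurements
#'
#' Computes, from an `n x k` 0/1 matrix, the variance `V` of the `n`
#' per-participant sums, the sum `S` of the `k` per-measurement
#' variances, Cronbach's \eqn{\alpha = k/(k-1)\,(1 - S/V)} and the
#' unitary correlation \eqn{\alpha_1 = (V - S)/((k-1)S)} — the mean
#' variance-weighted inter-measure correlation, linked to \eqn{\alpha}
#' by the Spearman-Brown relation (see [alpha_from_alpha1()]). In a
#' repeated-measures analysis, \eqn{\alpha_1} is the participant-related
#' share of the error variance that can be removed.
#'
#' @param x an `n x k` matrix or data frame of 0/1 values, `n >= 2`,
#'   `k >= 2`, no missing values.
#' @param variance_divisor `"n-1"` (sample variance, default) or `"n"`,
#'   applied to both `V` and the column variances.
#' @return An object of class `"anopa_consistency"`: a list with `V`,
#'   `S`, `k`, `n`, `alpha`, `alpha1`, and `degenerate` (`TRUE` when
#'   `V = 0` while `S > 0`, in which case `alpha1` is pinned at its
#'   algebraic minimum `-1/(k-1)`).
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(120, 1, 0.4), 30, 4)
#' consistency_stats(x)
#' @export
consistency_stats <- function(x, variance_divisor = c("n-1", "n")) {
  variance_divisor <- match.arg(variance_divisor)
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("entries must be 0 or 1", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (k < 2) stop("need at least 2 measurements", call. = FALSE)

  denom <- if (variance_divisor == "n-1") n - 1 else n
  rs <- rowSums(x)
  V <- sum((rs - mean(rs))^2) / denom
  cv <- colSums((x - matrix(colMeans(x), n, k, byrow = TRUE))^2) / denom
  S <- sum(cv)
  if (S == 0) {
    stop("degenerate data: all measurements are constant (S = 0)", call. = FALSE)
  }
  degenerate <- V == 0
  alpha1 <- if (degenerate) -1 / (k - 1) else (V - S) / ((k - 1) * S)
  # alpha from its defining ratio; the Spearman-Brown map has a pole at
  # alpha1 = -1/(k-1) (V = 0), where alpha diverges to -Inf
  alpha <- if (degenerate) -Inf else k / (k - 1) * (1 - S / V)
  if (degenerate) {
    warning("V = 0 with S > 0: alpha1 pinned at its minimum -1/(k-1)",
            call. = FALSE)
  }
  structure(list(V = V, S = S, k = k, n = n,
                 alpha = alpha, alpha1 = alpha1, degenerate = degenerate),
            class = "anopa_consistency")
}

#' @export
print.anopa_consistency <- function(x, digits = 4, ...) {
  cat("Consistency of", x$k, "repeated binary measurements on", x$n,
      "participants\n")
  cat("  V =", round(x$V, digits), "  S =", round(x$S, digits), "\n")
  cat("  Cronbach alpha =", round(x$alpha, digits),
      "  unitary alpha1 =", round(x$alpha1, digits), "\n")
  invisible(x)
}

#' Spearman-Brown link between Cronbach's alpha and the unitary alpha
#'
#' \eqn{\alpha = k\alpha_1 / (1 + (k-1)\alpha_1)} and its inverse
#' \eqn{\alpha_1 = \alpha / (k - (k-1)\alpha)}. The two maps are mutual
#' inverses away from the pole \eqn{\alpha_1 = -1/(k-1)}.
#'
#' @param alpha1,alpha the correlation on either scale.
#' @param k number of measurements, `>= 2`.
#' @return The correlation on the other scale.
#' @examples
#' alpha_from_alpha1(0.2881, 4)   # about 0.618
#' @export
alpha_from_alpha1 <- function(alpha1, k) {
  if (any(k < 2)) stop("'k' must be >= 2", call. = FALSE)
  den <- 1 + (k - 1) * alpha1
  if (any(abs(den) < 1e-12)) {
    stop("alpha1 = -1/(k-1) is the pole of the Spearman-Brown map", call. = FALSE)
  }
  k * alpha1 / den
}

#' @rdname alpha_from_alpha1
#' @export
alpha1_from_alpha <- function(alpha, k) {
  if (any(k < 2)) stop("'k' must be >= 2", call. = FALSE)
  den <- k - (k - 1) * alpha
  if (any(abs(den) < 1e-12)) stop("invalid alpha for this k", call. = FALSE)
  alpha / den
}
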