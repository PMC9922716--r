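#' Tukey HSD pairwise comparisons on transformed scores
#'
#' For every pair of cells, \eqn{q = |A_i - A_j| / \sqrt{\mathrm{MS}_e}}
#' is referred to the studentized-range distribution with `n_means`
#' groups and (effectively) infinite error degrees of freedom. When a
#' Williams correction factor is supplied, `q` is divided by
#' \eqn{\sqrt{c}} — the correction applies to the squared scale, so its
#' square root applies to a range statistic.
#'
#' @param A numeric vector of transformed cell scores (radians).
#' @param MSe shared error variance (radians squared), `> 0`.
#' @param labels optional cell labels.
#' @param n_means number of means the range is taken over (defaults to
#'   `length(A)`).
#' @param correction_c Williams correction factor (`1` = uncorrected).
#' @return A data frame, one row per pair sorted by decreasing `q`:
#'   labels, `diff` (radians), `q`, `p.value`, and when
#'   `correction_c > 1` also `q.corrected`, `p.corrected`.
#' @examples
#' a <- anscombe_transform(c(10, 14, 7, 5), c(30, 22, 18, 27))
#' tukey_hsd(a, mean(theoretical_variance(c(30, 22, 18, 27))))
#' @seealso [TukeyHSD.anopa()] for the fitted-object interface.
#' @export
tukey_hsd <- function(A, MSe, labels = NULL, n_means = length(A),
                      correction_c = 1) {
  if (length(A) < 2) stop("need at least 2 cells", call. = FALSE)
  if (!is.finite(MSe) || MSe <= 0) stop("'MSe' must be > 0", call. = FALSE)
  if (correction_c < 1) stop("'correction_c' must be >= 1", call. = FALSE)
  if (is.null(labels)) labels <- paste0("cell", seq_along(A))

  idx <- utils::combn(length(A), 2)
  d <- abs(A[idx[1, ]] - A[idx[2, ]])
  q <- d / sqrt(MSe)
  # the studentized-range cdf rejects df = Inf; 1e6 is indistinguishable
  pv <- stats::ptukey(q, n_means, 1e6, lower.tail = FALSE)
  out <- data.frame(
    cell1 = labels[idx[1, ]], cell2 = labels[idx[2, ]],
    diff = A[idx[1, ]] - A[idx[2, ]], q = q, p.value = pv,
    stringsAsFactors = FALSE)
  if (correction_c > 1) {
    out$q.corrected <- q / sqrt(correction_c)
    out$p.corrected <- stats::ptukey(out$q.corrected, n_means, 1e6,
                                     lower.tail = FALSE)
  }
  out[order(-out$q), , drop = FALSE]
}

#' Tukey HSD method for fitted analyses
#'
#' Runs [tukey_hsd()] on the fit's cells using its error term and, when
#' the fit was corrected, the Williams factor of the (first) effect row.
#'
#' @param x an `"anopa"` fit.
#' @param which,ordered,conf.level unused; kept for generic consistency.
#' @param ... unused.
#' @return See [tukey_hsd()].
#' @export
TukeyHSD.anopa <- function(x, which, ordered = FALSE, conf.level = 0.95, ...) {
  cc <- if (isTRUE(x$correction)) x$table$correction[1] else 1
  tukey_hsd(x$cells$A, x$MSe, labels = x$cells$label,
            n_means = x$n_means, correction_c = cc)
}

#' Linear contrast on transformed scores with known variances
#'
#' Tests \eqn{\sum w_i A_i = 0} with the known-variance z statistic
#' \eqn{z = \sum w_i A_i / \sqrt{\sum w_i^2 \mathrm{var_{th}}(A_i)}},
#' two-sided normal p-value. Each cell contributes its own theoretical
#' variance, so unequal sizes are handled exactly. No multiplicity
#' adjustment is applied; contrasts should be pre-specified.
#'
#' @param A numeric vector of transformed cell scores (radians).
#' @param var_th per-cell theoretical variances (radians squared).
#' @param weights contrast weights, summing to zero (tolerance 1e-9).
#' @return A list with `estimate` (radians), `z`, and `p.value`.
#' @examples
#' a <- anscombe_transform(c(10, 14, 7, 5), c(30, 22, 18, 27))
#' v <- theoretical_variance(c(30, 22, 18, 27))
#' linear_contrast(a, v, c(-1, 3, -1, -1))
#' @export
linear_contrast <- function(A, var_th, weights) {
  if (length(A) != length(weights) || length(A) != length(var_th)) {
    stop("'A', 'var_th' and 'weights' must have equal length", call. = FALSE)
  }
  if (abs(sum(weights)) > 1e-9) {
    stop("contrast weights must sum to zero", call. = FALSE)
  }
  est <- sum(weights * A)
  z <- est / sqrt(sum(weights^2 * var_th))
  list(estimate = est, z = z,
       p.value = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Contrast method for fitted analyses
#'
#' @param object an `"anopa"` fit.
#' @param weights contrast weights over the cells, summing to zero.
#' @return See [linear_contrast()].
#' @export
anopa_contrast <- function(object, weights) {
  if (!inherits(object, "anopa")) stop("'object' must be an anopa fit", call. = FALSE)
  linear_contrast(object$cells$A, object$cells$var_th, weights)
}
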