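#' Confidence intervals for proportions on the arcsine scale
#'
#' Builds \eqn{\gamma \times 100\%} intervals around each transformed
#' score, \eqn{A \pm m \, z_{(1+\gamma)/2} \, \mathrm{SE}} with
#' \eqn{\mathrm{SE} = 0.5/\sqrt{n + 1/2}}, and maps the limits back to
#' the proportion scale. The multiplier `m` encodes the intended use:
#' \describe{
#'   \item{`"none"`}{`m = 1`: a stand-alone interval, for comparing one
#'     result against a fixed value.}
#'   \item{`"difference"`}{`m = sqrt(2)`: widened so that inclusion of
#'     one cell's estimate in another cell's interval approximates a
#'     significance test of their difference (independent groups).}
#'   \item{`"correlation"`}{`m = sqrt(2 (1 - alpha1))`: repeated
#'     measures; positive inter-measure correlation shortens the bars.}
#' }
#' A-scale limits are clamped to \eqn{[0, \pi/2]} before
#' back-transformation; the `"precise"` inverse (default) undoes the
#' 3/8, 3/4 offsets.
#'
#' @param s,n success counts and cell sizes.
#' @param gamma confidence level in `(0, 1)`.
#' @param adjust `"none"`, `"difference"`, or `"correlation"`.
#' @param alpha1 unitary correlation, required (and `< 1`) for
#'   `adjust = "correlation"`.
#' @param labels optional cell labels.
#' @param back back-transformation mode, `"precise"` or `"naive"`.
#' @return A data frame with one row per cell: `label`, `s`, `n`, `p`,
#'   `A`, `SE`, `A.lower`, `A.upper`, `p.lower`, `p.upper`, `adjust`.
#' @examples
#' anopa_ci(c(10, 14, 7, 5), c(30, 22, 18, 27), adjust = "difference")
#' @export
anopa_ci <- function(s, n, gamma = 0.95,
                     adjust = c("none", "difference", "correlation"),
                     alpha1 = NULL, labels = NULL,
                     back = c("precise", "naive")) {
  adjust <- match.arg(adjust)
  back <- match.arg(back)
  check_counts(s, n)
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1) {
    stop("'gamma' must be inside (0, 1)", call. = FALSE)
  }
  mult <- switch(adjust,
    none = 1,
    difference = sqrt(2),
    correlation = {
      if (is.null(alpha1)) {
        stop("'alpha1' is required for the correlation adjustment", call. = FALSE)
      }
      if (!is.finite(alpha1) || alpha1 >= 1) {
        stop("degenerate: 'alpha1' must be < 1", call. = FALSE)
      }
      sqrt(2 * (1 - alpha1))
    })
  if (is.null(labels)) labels <- paste0("cell", seq_along(s))

  A <- anscombe_transform(s, n)
  SE <- 0.5 / sqrt(n + 0.5)
  hw <- mult * stats::qnorm((1 + gamma) / 2) * SE
  lo <- pmax(A - hw, 0)
  hi <- pmin(A + hw, pi / 2)
  data.frame(
    label = labels, s = s, n = n, p = s / n, A = A, SE = SE,
    A.lower = lo, A.upper = hi,
    p.lower = back_transform(lo, n, back),
    p.upper = back_transform(hi, n, back),
    adjust = adjust, stringsAsFactors = FALSE)
}
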