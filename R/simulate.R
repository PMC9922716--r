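#' Draw one between-subject sample
#'
#' Allocates a fixed total sample to `p` groups multinomially with
#' weights `(psi, 1, ..., 1)` (normalized) — `psi` is the prevalence of
#' the first group relative to each other group — then draws each cell's
#' success count binomially at its own probability. Allocations giving
#' any cell fewer than 2 observations are redrawn (at most 1000 tries).
#'
#' @param p number of groups.
#' @param pi success probability per group (scalar recycled, or length
#'   `p`), each in `(0, 1)`.
#' @param psi prevalence weight of the first group, `> 0`.
#' @param n_total total sample size.
#' @return A data frame with columns `s` and `n`, one row per group,
#'   with a `"retries"` attribute counting redraws.
#' @examples
#' set.seed(1)
#' gen_between_sample(4, c(0.32, 0.64, 0.40, 0.16), 1, 100)
#' @export
gen_between_sample <- function(p, pi, psi = 1, n_total = 100) {
  if (p < 2) stop("'p' must be >= 2", call. = FALSE)
  if (any(pi <= 0) || any(pi >= 1)) stop("'pi' must be inside (0, 1)", call. = FALSE)
  if (psi <= 0) stop("'psi' must be > 0", call. = FALSE)
  pi <- rep_len(pi, p)
  w <- c(psi, rep(1, p - 1)); w <- w / sum(w)
  n <- as.vector(stats::rmultinom(1, n_total, w))
  tries <- 0
  while (min(n) < 2) {
    tries <- tries + 1
    if (tries > 1000) stop("could not allocate >= 2 per cell in 1000 tries", call. = FALSE)
    n <- as.vector(stats::rmultinom(1, n_total, w))
  }
  out <- data.frame(s = stats::rbinom(p, n, pi), n = n)
  attr(out, "retries") <- tries
  out
}

#' Draw one within-subject sample of exchangeable correlated binaries
#'
#' Each participant gets a shared Bernoulli(`pi`) anchor; each of the
#' `k` measurements copies the anchor with probability `sqrt(rho)` and
#' is otherwise an independent Bernoulli(`pi`) draw. This gives every
#' column the exact marginal `pi` and every pair of columns the exact
#' exchangeable correlation `rho` (the covariance of two columns with
#' copy probability `c` is `c^2 pi (1 - pi)`).
#'
#' @param k number of repeated measurements.
#' @param pi marginal success probability, in `(0, 1)`.
#' @param rho exchangeable pairwise correlation, in `[0, 1)`.
#' @param n number of participants.
#' @return An `n x k` 0/1 matrix.
#' @examples
#' set.seed(1)
#' x <- gen_within_sample(4, 0.3, 0.2, 1000)
#' colMeans(x)
#' @export
gen_within_sample <- function(k, pi, rho, n) {
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  if (pi <= 0 || pi >= 1) stop("'pi' must be inside (0, 1)", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  anchor <- stats::rbinom(n, 1, pi)
  copy <- matrix(stats::rbinom(n * k, 1, sqrt(rho)), n, k)
  indep <- matrix(stats::rbinom(n * k, 1, pi), n, k)
  copy * anchor + (1 - copy) * indep
}

#' Monte-Carlo rejection-rate study
#'
#' Repeatedly generates samples under a fully specified population,
#' runs the matching omnibus test, and tallies how often the null is
#' rejected at level `alpha`. With equal cell probabilities the rate
#' estimates the type I error; with unequal probabilities, power.
#' Between-subject designs are fully vectorized across replications.
#'
#' @param design `"oneway"`, `"twoway"`, or `"within"`.
#' @param pi cell success probabilities: length `p` (oneway), a `p x q`
#'   matrix or length `p*q` vector (twoway), or a scalar marginal
#'   (within).
#' @param n_total total sample size (between designs).
#' @param p,q numbers of factor levels (inferred from `pi` when it has
#'   length/shape).
#' @param psi prevalence weight of the first cell (between designs).
#' @param k,n,rho within designs: number of measurements, participants,
#'   and exchangeable correlation.
#' @param reps number of replications.
#' @param alpha decision threshold.
#' @param correction apply the Williams correction before tallying.
#' @param seed optional integer seed (set once for the whole study).
#' @return An object of class `"anopa_mc"`: a list with `rate`, `se`
#'   (binomial Monte-Carlo standard error), `reps`, `retries`
#'   (allocation redraws), and the configuration.
#' @examples
#' anopa_mc("oneway", pi = c(0.32, 0.64, 0.40, 0.16), n_total = 100,
#'          reps = 2000, seed = 1)
#' @export
anopa_mc <- function(design = c("oneway", "twoway", "within"),
                     pi, n_total = NULL, p = NULL, q = NULL, psi = 1,
                     k = NULL, n = NULL, rho = 0,
                     reps = 10000, alpha = 0.05, correction = TRUE,
                     seed = NULL) {
  design <- match.arg(design)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- switch(design,
    oneway = mc_oneway(pi, psi, n_total, reps, alpha, correction),
    twoway = mc_twoway(pi, p, q, psi, n_total, reps, alpha, correction),
    within = mc_within(pi, k, n, rho, reps, alpha, correction))
  structure(c(res, list(
    design = design, alpha = alpha, correction = correction,
    config = list(pi = pi, psi = psi, n_total = n_total, p = p, q = q,
                  k = k, n = n, rho = rho, reps = reps, seed = seed))),
    class = "anopa_mc")
}

#' @export
print.anopa_mc <- function(x, ...) {
  cat("Monte-Carlo study (", x$design, "), ", x$reps, " replications\n", sep = "")
  cat("  rejection rate at alpha = ", x$alpha, ": ",
      format(x$rate, digits = 4), "  (MC SE ", format(x$se, digits = 3),
      ")\n", sep = "")
  if (x$retries > 0) cat("  allocation redraws:", x$retries, "\n")
  invisible(x)
}

# vectorized multinomial allocation with redraw of cells below min size
draw_sizes <- function(reps, n_total, w, min_cell = 2) {
  ns <- t(stats::rmultinom(reps, n_total, w))
  retries <- 0
  repeat {
    bad <- which(apply(ns, 1, min) < min_cell)
    if (!length(bad)) break
    retries <- retries + length(bad)
    if (retries > 1000 * reps) {
      stop("could not allocate >= ", min_cell, " per cell", call. = FALSE)
    }
    ns[bad, ] <- t(stats::rmultinom(length(bad), n_total, w))
  }
  list(ns = ns, retries = retries)
}

mc_oneway <- function(pi, psi, n_total, reps, alpha, correction) {
  p <- length(pi)
  if (p < 2) stop("oneway needs length(pi) >= 2", call. = FALSE)
  if (is.null(n_total)) stop("'n_total' is required", call. = FALSE)
  w <- c(psi, rep(1, p - 1)); w <- w / sum(w)
  al <- draw_sizes(reps, n_total, w)
  ns <- al$ns
  s <- matrix(stats::rbinom(reps * p, as.vector(ns), rep(pi, each = reps)),
              reps, p)
  a <- asin(sqrt((s + 3 / 8) / (ns + 3 / 4)))
  MS <- (rowSums(a^2) - rowSums(a)^2 / p) / (p - 1)
  MSe <- rowMeans(1 / (4 * (ns + 0.5)))
  g <- (p - 1) * MS / MSe
  if (correction) g <- g / williams_correction(p - 1, p, n_total)
  tally(stats::pchisq(g, p - 1, lower.tail = FALSE) < alpha, reps, al$retries)
}

mc_twoway <- function(pi, p, q, psi, n_total, reps, alpha, correction) {
  if (is.matrix(pi)) { p <- nrow(pi); q <- ncol(pi); pi <- as.vector(t(pi)) }
  if (is.null(p) || is.null(q) || length(pi) != p * q) {
    stop("supply 'pi' as a p x q matrix, or 'p' and 'q' with length(pi) = p*q",
         call. = FALSE)
  }
  if (is.null(n_total)) stop("'n_total' is required", call. = FALSE)
  m <- p * q
  w <- c(psi, rep(1, m - 1)); w <- w / sum(w)
  al <- draw_sizes(reps, n_total, w)
  ns <- al$ns
  s <- matrix(stats::rbinom(reps * m, as.vector(ns), rep(pi, each = reps)),
              reps, m)
  a <- asin(sqrt((s + 3 / 8) / (ns + 3 / 4)))   # columns in row-major (i,j) order
  gm <- rowMeans(a)
  rowm <- vapply(seq_len(p), function(i)
    rowMeans(a[, ((i - 1) * q + 1):(i * q), drop = FALSE]), numeric(reps))
  colm <- vapply(seq_len(q), function(j)
    rowMeans(a[, seq(j, m, by = q), drop = FALSE]), numeric(reps))
  SSB <- rowSums((a - gm)^2)
  SSP <- q * rowSums((rowm - gm)^2)
  SSQ <- p * rowSums((colm - gm)^2)
  SSPQ <- SSB - SSP - SSQ
  dfPQ <- (p - 1) * (q - 1)
  MSe <- rowMeans(1 / (4 * (ns + 0.5)))
  g <- SSPQ / MSe   # interaction test, the focus of two-way calibration
  if (correction) g <- g / williams_correction(dfPQ, m, n_total)
  tally(stats::pchisq(g, dfPQ, lower.tail = FALSE) < alpha, reps, al$retries)
}

mc_within <- function(pi, k, n, rho, reps, alpha, correction) {
  if (is.null(k) || is.null(n)) stop("'k' and 'n' are required", call. = FALSE)
  if (length(pi) != 1) stop("within designs use a scalar marginal 'pi'", call. = FALSE)
  cc <- if (correction) williams_correction(k - 1, k, n * k) else 1
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    x <- gen_within_sample(k, pi, rho, n)
    cs <- tryCatch(suppressWarnings(consistency_stats(x)),
                   error = function(e) NULL)
    if (is.null(cs) || cs$alpha1 >= 1) { rej[r] <- FALSE; next }
    A <- asin(sqrt((colSums(x) + 3 / 8) / (n + 3 / 4)))
    MSe <- (1 - cs$alpha1) / (4 * (n + 0.5))
    g <- (k - 1) * stats::var(A) / MSe / cc
    rej[r] <- stats::pchisq(g, k - 1, lower.tail = FALSE) < alpha
  }
  tally(rej, reps, 0)
}

tally <- function(rej, reps, retries) {
  rate <- mean(rej)
  list(rate = rate, se = sqrt(rate * (1 - rate) / reps),
       reps = reps, retries = retries)
}
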