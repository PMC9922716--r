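#' @export
print.anopa <- function(x, digits = 4, ...) {
  design <- switch(x$design,
                   oneway = "One-way between-subject",
                   twoway = "Two-way between-subject",
                   within = "One-way repeated-measures")
  cat(design, "analysis of proportions (arcsine scale)\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("\n")
  tab <- x$table
  out <- data.frame(
    SS = round(tab$SS, digits), df = tab$df, MS = round(tab$MS, digits),
    F = round(tab$F, digits), `p-value` = round(tab$p.value, digits),
    check.names = FALSE, row.names = tab$effect)
  if (x$correction) {
    out$`F(corr)` <- round(tab$F.corrected, digits)
    out$`p(corr)` <- round(tab$p.corrected, digits)
  }
  err <- data.frame(SS = NA, df = Inf, MS = round(x$MSe, digits), F = NA,
                    `p-value` = NA, check.names = FALSE, row.names = "Error")
  if (x$correction) { err$`F(corr)` <- NA; err$`p(corr)` <- NA }
  print(rbind(out, err), na.print = "-")
  if (!is.null(x$alpha1)) {
    cat("\nUnitary inter-measure correlation alpha1 =",
        round(x$alpha1, digits), "\n")
  }
  invisible(x)
}

#' Summarize an analysis of proportions
#'
#' Adds the observed effect size (for single-factor between designs) and
#' the cell table to the test table.
#'
#' @param object an `"anopa"` fit.
#' @param ... unused.
#' @return An object of class `"summary.anopa"`.
#' @export
summary.anopa <- function(object, ...) {
  es <- NULL
  if (object$design == "oneway") {
    es <- observed_effect_size(object)
  }
  structure(list(fit = object, effect_size = es), class = "summary.anopa")
}

#' @export
print.summary.anopa <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCells:\n")
  print(cbind(x$fit$cells[c("label", "s", "n")],
              p = round(x$fit$cells$p, digits),
              A = round(x$fit$cells$A, digits)), row.names = FALSE)
  if (!is.null(x$effect_size)) {
    cat("\nEffect size: f2 =", round(x$effect_size$f2, digits),
        " eta2 =", round(x$effect_size$eta2, digits), "\n")
  }
  invisible(x)
}

#' @export
coef.anopa <- function(object, ...) {
  stats::setNames(object$cells$A, object$cells$label)
}

#' Confidence intervals for the cells of a fitted analysis
#'
#' Delegates to [anopa_ci()]. The default adjustment matches the design:
#' difference-adjusted for between-subject fits, correlation- and
#' difference-adjusted (using the estimated \eqn{\alpha_1}) for
#' repeated-measures fits.
#'
#' @param object an `"anopa"` fit.
#' @param parm ignored (all cells are returned).
#' @param level confidence level.
#' @param adjust `"difference"`, `"correlation"`, or `"none"`.
#' @param ... passed to [anopa_ci()].
#' @return The [anopa_ci()] data frame.
#' @export
confint.anopa <- function(object, parm, level = 0.95, adjust = NULL, ...) {
  if (is.null(adjust)) {
    adjust <- if (object$design == "within") "correlation" else "difference"
  }
  anopa_ci(object$cells$s, object$cells$n, gamma = level, adjust = adjust,
           alpha1 = object$alpha1, labels = object$cells$label, ...)
}

#' Plot cell proportions with adjusted confidence intervals
#'
#' Proportions are drawn on an arcsine-spaced vertical axis (the
#' transformed scores are what is linear), with error bars from
#' [confint.anopa()].
#'
#' @param x an `"anopa"` fit.
#' @param level confidence level for the error bars.
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.anopa <- function(x, level = 0.95, ...) {
  ci <- stats::confint(x, level = level)
  k <- nrow(ci)
  at <- seq_len(k)
  ticks <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99)
  graphics::plot(at, ci$A, xlim = c(0.5, k + 0.5), ylim = c(0, pi / 2),
                 xaxt = "n", yaxt = "n", xlab = "", pch = 19,
                 ylab = "proportion (arcsine-spaced axis)", ...)
  graphics::axis(1, at = at, labels = ci$label)
  graphics::axis(2, at = asin(sqrt(ticks)), labels = ticks, las = 1)
  graphics::arrows(at, ci$A.lower, at, ci$A.upper,
                   angle = 90, code = 3, length = 0.05)
  invisible(x)
}

#' Simulate replicate datasets from a fitted analysis
#'
#' Between-subject fits resample each cell's count binomially at the
#' observed proportion and size; repeated-measures fits draw exchangeable
#' correlated binaries via [gen_within_sample()] at the observed marginal
#' proportions and the estimated \eqn{\alpha_1}.
#'
#' @param object an `"anopa"` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of data frames (between) or 0/1 matrices (within).
#' @export
simulate.anopa <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cells <- object$cells
  if (object$design == "within") {
    rho <- max(object$alpha1, 0)
    # exchangeable draw at the mean marginal rate: occasion-specific
    # rates are not preserved, only the common level and correlation
    lapply(seq_len(nsim), function(i) {
      m <- gen_within_sample(nrow(cells), mean(cells$p), rho, cells$n[1])
      colnames(m) <- cells$label
      m
    })
  } else {
    lapply(seq_len(nsim), function(i) {
      data.frame(label = cells$label,
                 s = stats::rbinom(nrow(cells), cells$n, cells$p),
                 n = cells$n, stringsAsFactors = FALSE)
    })
  }
}
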