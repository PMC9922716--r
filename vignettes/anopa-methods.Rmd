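---
title: "Analyzing proportions on the arcsine scale: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing proportions on the arcsine scale: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anopa)
```

## The problem

A binary outcome summarized as a proportion $p = s/n$ is an awkward
dependent variable: its variance $\pi(1-\pi)/n$ depends on the very
quantity being compared, and its sampling distribution is skewed away
from $\pi = 0.5$. Group comparisons on raw proportions therefore
violate homoscedasticity by construction, and none of the exact
single- or two-group tests generalize to factorial or repeated-measure
layouts.

This package takes the variance-stabilization route. Each cell's count
is aggregated through the Anscombe arcsine transform

$$A = \sin^{-1}\sqrt{\frac{s + 3/8}{n + 3/4}},$$

whose large-sample variance,

$$\mathrm{var_{th}}(A) = \frac{1}{4\,(n + 1/2)},$$

depends only on the cell size — not on the underlying probability. An
error variance that is known rather than estimated changes the logic
of the ANOVA decomposition in one essential way: the error term has no
sampling uncertainty, so the reference distribution of an effect's
mean square against it is chi-square, not F with finite denominator
degrees of freedom. We report $F = \mathrm{MS}_{effect}/\mathrm{MS}_e$
with denominator df shown as $\infty$, and compute every p-value from
$g = \mathrm{df}\times F \sim \chi^2_{\mathrm{df}}$, which avoids any
software-specific handling of infinite df.

## The decomposition

**One-way between.** With $p$ cells, $\mathrm{SS}_P = \sum_i (A_i -
\bar A)^2 = (p-1)\,\mathrm{var}(A_i)$ and $\mathrm{MS}_P =
\mathrm{var}(A_i)$ — note there is no multiplication by $n$, because
the $A_i$ are cell aggregates, not participant means. The error term
is the mean of the cellwise theoretical variances,
$\mathrm{MS}_e = \tfrac1p \sum_i 1/(4(n_i + 1/2))$. A harmonic-mean
shortcut $1/(4(\tilde n + 1/2))$ is available (`mse = "harmonic"`) but
the exact mean is the default: it is just as cheap and reproduces the
published analyses.

**Two-way between.** Cell scores $A_{ij}$ decompose through
*unweighted* marginal means: each cell counts once regardless of its
size. This is a deliberate choice — the transform has already absorbed
the cell sizes into the (known) error variances, so size-weighted
marginals would double-count $n$. The interaction sum of squares is
obtained by subtraction from the between-cell total; the
decomposition $\mathrm{SS}_{Between} = \mathrm{SS}_P + \mathrm{SS}_Q +
\mathrm{SS}_{P\times Q}$ is exact and tested to $10^{-10}$.

**One-way within.** Repeated binary measurements are correlated across
occasions. The package measures that correlation with the *unitary*
coefficient $\alpha_1$, derived from Cronbach's $\alpha$ through the
Spearman–Brown relation:

$$\alpha_1 = \frac{V - S}{(k-1)\,S},$$

where $V$ is the variance of the per-participant sums and $S$ the sum
of the per-occasion variances. $\alpha_1$ is the participant-related
share of the error variance, and removing it gives the purer error
term $\mathrm{MS}_e = (1-\alpha_1)/(4(n+1/2))$. When $\alpha_1 = 0$
this is exactly the between-subject error; when $\alpha_1 < 0$
(possible, e.g. with compensatory response patterns) the error term is
*inflated* — the formula is applied as is, with a warning, rather than
truncating at zero.

Two numerical conventions here were genuinely open:

* **Variance divisor.** Whether $V$ and $S$ use $n$ or $n-1$ is
  immaterial for $\alpha_1$ (the common factor cancels in the ratio),
  but matters for reporting $V$ and $S$ themselves. The default is the
  sample variance ($n-1$), exposed as `variance_divisor`.
* **Degenerate inputs.** All-constant columns ($S = 0$) are an error —
  no correlation is estimable. $V = 0$ with $S > 0$ (perfectly
  compensating patterns) pins $\alpha_1$ at its algebraic minimum
  $-1/(k-1)$, flagged, where Cronbach's $\alpha$ diverges to
  $-\infty$; the Spearman–Brown map has a pole there, so $\alpha$ is
  computed from its defining ratio, never through the map.

## Small-sample correction

For moderate samples the chi-square form shows a mild excess of
rejections (up to about 1.3 points above the nominal 5%). Williams'
correction divides the statistic by

$$c = 1 + \frac{m^2 - 1}{6\,N\,\mathrm{df}},$$

with $m$ the number of cells involved in the effect and $N$ the total
observation count. $c \ge 1$ always, so corrected p-values are never
smaller than uncorrected ones; $c \to 1$ as $N$ grows. Range
statistics (Tukey HSD) are divided by $\sqrt{c}$, since the correction
is defined on the squared scale. The published worked values (1.0086
for a four-group study of 97 participants; the repeated-measure
p-value moving from 0.0276 to 0.0284 over $N = 30\times4$
observations) pin down $N$ as the *total* count; a reading of the
formula with a per-group harmonic mean instead reproduces neither, so
the total-count convention is used throughout.

## Post-hoc machinery

Pairwise comparisons use the studentized range
$q = |A_i - A_j|/\sqrt{\mathrm{MS}_e}$ with the number of means of the
design and infinite error df, realized numerically as `df = 1e6`
(distribution routines reject literal infinity; the approximation
error on p is below $10^{-6}$). Linear contrasts use the
known-variance z statistic with each cell's own theoretical variance,
so unequal sizes are exact; a full orthogonal set of $p-1$ contrasts
with equal $n$ reconstitutes the omnibus $g$, which the test suite
verifies. No multiplicity adjustment is layered on top of HSD, and
contrasts are reported unadjusted: the intended workflow is a small
number of pre-specified contrasts.

## Effect sizes and planning

The observed effect size is $f^2 = \mathrm{MS}_P / (\tilde n\,
\mathrm{MS}_e)$ — dividing by the harmonic mean size converts the
aggregate-level ratio into a per-observation one. For planning,
expected proportions are transformed and
$f^2 = 4\frac{p-1}{p}\mathrm{var}(A_i)$: the $(p-1)/p$ factor makes
the variance a population quantity, and the 4 is the reciprocal of the
per-observation error variance $1/4$. Two variants exist: with a
planned per-group $n$ the full offset transform is used (counts are
rounded to integers, with a warning if rounding moves them by more
than 0.01), and without $n$ the size-free $\sin^{-1}\sqrt{\pi}$ is
used.

The noncentrality is $\lambda = n_{total} f^2$ and power is the
noncentral chi-square tail above the central critical value.
`required_n()` inverts this for a target power. Its default reference
distribution deserves a note: the chi-square (infinite-df) form
matches the test the package actually performs, but standard power
software evaluates the noncentral F with denominator df $N - p$, and
published planning numbers follow that convention (the worked
replication plan asks for 92 participants, where the infinite-df form
would ask for 88). `required_n()` therefore defaults to the
noncentral-F convention (`denominator = "fdist"`), holds $f^2$ fixed
at the planning estimate across candidate sizes — re-deriving it at
every candidate $n$ makes power non-monotone through count rounding —
and rounds the exact solution up to equal groups.

A separate rule of thumb guards calibration rather than power: the
test holds its nominal level only once the empirical variance of the
transform matches the theoretical one, at roughly

$$n_{sufficient} = \lceil 20p + 50\,|\sin^{-1}(p_{extreme}) -
\sin^{-1}(0.5)| \rceil$$

total observations (the arcsine applied to the proportion itself, as
this rule was stated and worked through — with $\sqrt{p}$ inside, the
published worked values 97 and 99 do not reproduce). Fits below this
threshold emit an advisory message, never an error; the same advisory
policy applies to group-size ratios above 1.5.

## Confidence intervals

The standard error of a transformed score is $0.5/\sqrt{n + 1/2}$ and
the Gaussian quantile applies (the error variance being known, there
is no t correction to make). Three interval flavours differ only in a
width multiplier: 1 for stand-alone use, $\sqrt 2$ when intervals are
meant to be compared pairwise across independent groups (inclusion of
one estimate in another's interval then approximates a difference
test), and $\sqrt{2(1-\alpha_1)}$ for repeated measures, where
positive correlation legitimately shortens the bars. At
$\alpha_1 = 0.5$ the correlation-adjusted interval coincides with the
stand-alone one.

Limits are computed on the $A$ scale, clamped to $[0, \pi/2]$ (small
cells can push a limit outside the admissible range), and mapped back
to proportions. The precise inverse $((n + 3/4)\sin^2 A - 3/8)/n$ is
the default — it is the exact inverse of the forward transform and
reproduces the published interval endpoints where the plain $\sin^2$
does not. `plot()` draws proportions on an arcsine-spaced axis so the
intervals remain visually symmetric.

A known limitation: coverage of any interval for a discrete outcome
oscillates with $n$ and $\pi$. At $n = 50$, $\pi = 0.5$ the exact
coverage of the 95% interval is 93.5% — outside the 94.2–95.8% band
often quoted for arcsine intervals. The test suite computes coverage
over a fixed $(n, \pi)$ grid and records this: the band holds at most,
not all, grid points.

## The Monte-Carlo engine

`gen_between_sample()` fixes the total $N$ and allocates it
multinomially, with a prevalence weight $\psi$ for the first group
(weights $\psi, 1, \dots, 1$ normalized) — mirroring how participants
actually arrive in unequal groups. Allocations leaving any cell below
2 observations are redrawn and counted. `gen_within_sample()` builds
exchangeable correlated binaries: a participant-level Bernoulli($\pi$)
anchor, copied by each occasion with probability $\sqrt\rho$ and
otherwise replaced by an independent Bernoulli($\pi$) draw. The copy
probability is $\sqrt\rho$, not $\rho$, because the covariance of two
occasions with copy probability $c$ is $c^2\pi(1-\pi)$: this
construction delivers marginal $\pi$ and pairwise correlation $\rho$
*exactly*, which the suite verifies by recovering $\rho$ from
$\hat\alpha_1$ at large $n$. It is a stand-in for whatever mechanism a
given real process follows; only the first two moments are matched.

`anopa_mc()` runs generate–test–tally loops, fully vectorized across
replications for the between designs (100,000 one-way replications
take about two seconds). Study sizes in the shipped tests were chosen
as desk-scale versions of the published simulation designs: 100,000
replications per condition (Monte-Carlo SE $\approx 0.0007$ at a rate
of 0.05) on a reduced grid $p \in \{2,4\}$, $\pi \in \{0.3, 0.5\}$,
$\psi \in \{1, 2\}$, $n_{total} \in \{100, 400\}$, rather than the
full 960-condition, 500,000-replication grids of the original studies.
Stochastic assertions compare rates to their targets within three
Monte-Carlo standard errors; small-sample conservatism is asserted
strictly, at the four-group condition where it is an unambiguous
prediction (at $p = 2$ and $n_{total} = 20$, discreteness leaves the
rate hovering at 0.052 rather than below 0.05).

## What the synthetic data do and do not show

The generators emulate exactly the populations the analytical theory
assumes: independent binomial cells with a fixed total and, within
subjects, an exchangeable correlation structure with a common
marginal. Real data depart from this in ways the simulations do not
probe — occasion-specific marginals, non-exchangeable correlation
(e.g. decaying with lag), overdispersion from unmodelled
heterogeneity, and missingness (the within-design fit requires
complete cases and does not impute). Passing calibration on the
synthetic grid therefore supports the arithmetic and the asymptotic
claims, not robustness to those departures.

## Reproducing the published analyses

```{r example}
incubation <- data.frame(
  group = c("Crossword", "Sudoku", "Chant", "Breath"),
  s = c(10, 14, 7, 5), n = c(30, 22, 18, 27))
fit <- anopa(cbind(s, n) ~ group, incubation)
fit
TukeyHSD(fit)[1, ]
observed_effect_size(fit)$f2
```

The repository's `scripts/acceptance.R` re-runs all headline numbers
(transforms, mean squares, the factorial F, sufficient sizes, the
planning pipeline, and the Monte-Carlo power study) from scratch and
writes them to JSON.
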