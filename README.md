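# anopa

ANOVA-style analysis of proportions on the Anscombe arcsine scale, for
researchers whose dependent variable is a binary outcome (success or
failure) observed in groups, factorial designs, or repeated measures.

## The idea

A proportion's variance depends on the proportion itself, so comparing
raw proportions across groups violates homoscedasticity from the
start. The Anscombe transform

    A = asin( sqrt( (s + 3/8) / (n + 3/4) ) )

maps a count of `s` successes out of `n` to a score whose asymptotic
variance, `1/(4(n + 1/2))`, depends only on the cell size. Because the
error variance is *known* rather than estimated, ANOVA-style sums of
squares on the transformed cell scores can be tested against a
chi-square reference with infinite error degrees of freedom:
`g = df × F` is a central chi-square on the effect's df under the
null. Around this core the package provides:

- one-way and two-way between-subject tests, and one-way
  repeated-measures tests with the error deflated by the unitary
  inter-measure correlation α₁;
- Williams' small-sample correction `c = 1 + (m² − 1)/(6 N df)`;
- Tukey HSD pairwise comparisons and known-variance linear contrasts;
- effect sizes (f², η²), noncentral chi-square/F power analysis,
  required and sufficient sample sizes;
- stand-alone, difference-adjusted (√2) and correlation-adjusted
  (√(2(1−α₁))) confidence intervals on both scales;
- a vectorized Monte-Carlo engine for type-I-error and power studies.

## Worked example

Four groups solve a problem after different distraction tasks; the
outcome is whether each participant found the optimal solution.

```r
library(anopa)
incubation <- data.frame(
  group = c("Crossword", "Sudoku", "Chant", "Breath"),
  s = c(10, 14, 7, 5), n = c(30, 22, 18, 27))
fit <- anopa(cbind(s, n) ~ group, incubation)
fit
#>           SS  df     MS      F p-value F(corr) p(corr)
#> group 0.1104   3 0.0368 3.5124  0.0145  3.4825  0.0151
#> Error     NA Inf 0.0105     NA      NA      NA      NA
```

The distraction task affects the success rate (F(3, ∞) = 3.51,
p = 0.0145; the corrected columns divide by Williams' factor, here
1.0086). The error mean square 0.0105 is the average of the four
theoretical variances — no degrees of freedom were spent estimating
it. Pairwise comparisons locate the difference:

```r
TukeyHSD(fit)[1, c("cell1", "cell2", "q", "p.value")]
#>    cell1  cell2        q     p.value
#>   Sudoku Breath 4.524392 0.007528943
```

and the observed effect size is moderate-to-large:

```r
observed_effect_size(fit)$f2
#> [1] 0.1504899
```

Planning a replication with expected proportions 0.32, 0.64, 0.40,
0.16 at 25 per group:

```r
f2 <- planning_f2(c(0.32, 0.64, 0.40, 0.16), 25)  # 0.1280757
power_from_lambda(noncentrality(100, f2), df_effect = 3)
#> [1] 0.8652951
required_n(f2, p = 4)$n_total
#> [1] 92
```

Repeated measures use a 0/1 matrix (one column per occasion), or the
published counts plus a known correlation:

```r
anopa_within_counts(c(15, 6, 8, 10), 30, alpha1 = 0.2881)
#>           SS  df     MS     F p-value F(corr) p(corr)
#> P     0.0534   3 0.0178 3.049  0.0274   3.028  0.0282
#> Error     NA Inf 0.0058    NA      NA      NA      NA
```

## Documentation

The methods vignette (`vignettes/anopa-methods.Rmd`) explains the
model, the error-term conventions, the correction factor, the planning
conventions, the interval adjustments, and the design and limits of
the simulation engine.
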