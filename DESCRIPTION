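Package: anopa
Title: Analysis of Proportions Using the Anscombe Arcsine Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Omnibus and post-hoc tests, effect sizes, power planning,
    adjusted confidence intervals and Monte-Carlo calibration studies for
    binomial proportions, built on the Anscombe arcsine transform. The
    transform stabilizes the variance of a proportion at the theoretically
    known value 1/(4(n+1/2)), so ANOVA-style decompositions of transformed
    scores can be tested against a chi-square reference with no error
    degrees of freedom estimated from the data. Supports one-way and
    two-way between-subject designs and one-way repeated-measure designs,
    Williams' small-sample correction, Tukey HSD pairwise comparisons,
    linear contrasts, noncentral chi-square/F power analysis, and
    difference- and correlation-adjusted confidence intervals on both the
    transformed and the proportion scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
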