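# worked-example fixtures, built in code

# incubation experiment: four distraction groups, success = optimal choice
incubation <- data.frame(
  group = c("Crossword", "Sudoku", "Chant", "Breath"),
  s = c(10, 14, 7, 5),
  n = c(30, 22, 18, 27),
  stringsAsFactors = FALSE
)

# graduation study: 2 (moment of diagnosis) x 3 (SES) between design
graduation <- data.frame(
  moment = rep(c("early", "late"), 3),
  ses = rep(c("low", "mid", "high"), each = 2),
  s = c(75, 84, 62, 52, 40, 42),
  n = c(89, 92, 77, 72, 52, 63),
  stringsAsFactors = FALSE
)

# delirium drug study: 4 repeated measurements on 30 participants
delirium_counts <- c(cBeau = 15, eaPoe = 6, RV = 8, placebo = 10)
delirium_n <- 30
delirium_V <- 1.5966
delirium_S <- 0.8563
delirium_alpha1 <- (delirium_V - delirium_S) / (3 * delirium_S)

fit_incubation <- function(...) {
  suppressMessages(anopa_oneway(incubation$s, incubation$n,
                                labels = incubation$group, ...))
}
fit_graduation <- function(...) {
  suppressMessages(anopa_twoway(graduation$s, graduation$n,
                                graduation$moment, graduation$ses, ...))
}
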