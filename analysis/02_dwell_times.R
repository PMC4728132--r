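#!/usr/bin/env Rscript
# Dwell-time (retention) analysis at the peak center: simulated decay
# half-times of the Bem1-GEF and Cdc42 pools under clamped partner
# concentrations, against the quasi-steady-state closed forms.

suppressMessages(library(polarcomp))
dir.create("results", showWarnings = FALSE)

p <- default_parameters()

bem <- dwell_time_sweep("BemGEF", seq(0, 450, 50), p)
cdc <- dwell_time_sweep("Cdc42", seq(0, 40, 5), p)
write.csv(bem, "results/dwell_bemgef.csv", row.names = FALSE)
write.csv(cdc, "results/dwell_cdc42.csv", row.names = FALSE)

fit <- lm(t_half_sim ~ partner, bem)
message(sprintf(
  "Bem1-GEF dwell: slope %.4f s/uM (QSSA %.4f), R^2 = %.5f",
  coef(fit)[2], log(2) * p$k4a / (p$k1b * p$k4b),
  summary(fit)$r.squared))
fit2 <- lm(t_half_sim ~ partner, cdc)
message(sprintf(
  "Cdc42 dwell:    slope %.4f s/uM (QSSA %.4f), R^2 = %.5f",
  coef(fit2)[2], log(2) * p$k3 / (p$k2b * p$k5b),
  summary(fit2)$r.squared))
message(sprintf(
  "recruitment rate at 0.01 uM cytosolic GEF, 450 uM Cdc42T: %.1f uM/s",
  recruitment_rate(0.01, 450, p)))
message("wrote results/dwell_{bemgef,cdc42}.csv")
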