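#!/usr/bin/env Rscript
# Stage 1 — two-state photophysics of the glycan-binding dye.
# Builds the default synthetic dye (13 nm absorbance / 14 nm emission red
# shift, turn-on contrast calibrated to 7.3 at 561 nm ex / 575 nm longpass)
# and tabulates the contrast at common confocal settings.

suppressMessages(library(glycoprobe))

dir.create("results", showWarnings = FALSE)
dye <- make_default_dye()
write_dye_model(dye, "results/dye_model")

settings <- list(
  rfp_561_575lp   = acquisition_settings(561, c(575, Inf)),
  red_561_575_630 = acquisition_settings(561, c(575, 630)),
  gfp_488_500_545 = acquisition_settings(488, c(500, 545)),
  yellow_514_530_560 = acquisition_settings(514, c(530, 560)))

tab <- data.frame(
  setting = names(settings),
  excitation_nm = vapply(settings, `[[`, numeric(1), "excitation_nm"),
  band_low_nm = vapply(settings, function(s) s$emission_band[1], numeric(1)),
  band_high_nm = vapply(settings, function(s) s$emission_band[2], numeric(1)),
  unbound_signal = vapply(settings, function(s)
    signal_at_settings(dye, 0, s), numeric(1)),
  bound_signal = vapply(settings, function(s)
    signal_at_settings(dye, 1, s), numeric(1)))
tab$contrast_dff <- contrast_dff(tab$bound_signal, tab$unbound_signal)
write_table(tab, "results/photophysics_contrast.csv")

cat("Fluorogenic contrast (delta F / F) by acquisition setting:\n")
print(tab[, c("setting", "contrast_dff")], row.names = FALSE)
cat("\nThe RFP-style setting (561 nm ex, 575 nm longpass) realizes the",
    "\ncalibrated turn-on of", sprintf("%.2f", tab$contrast_dff[1]),
    "; green (GFP-style) settings invert the contrast\nbecause they",
    "preferentially excite and collect the unbound state.\n")
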