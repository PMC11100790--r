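#!/usr/bin/env Rscript
# Stage 6 — photostability over a 9.6 h timelapse at 1 frame/min.
# Compares the reversible-exchange regime (excess free dye replenishes
# photobleached bound dye) with irreversible bleaching of the same
# bound-state bleach rate.

suppressMessages(library(glycoprobe))
dir.create("results", showWarnings = FALSE)

tr_on <- simulate_photostability(exchange = TRUE, seed = 1)
tr_off <- simulate_photostability(exchange = FALSE, seed = 2)
m_on <- bleaching_metric(tr_on)
m_off <- bleaching_metric(tr_off)

tab <- data.frame(
  regime = c("exchange_on", "exchange_off"),
  relative_change = c(m_on$relative_change, m_off$relative_change),
  slope_per_hour = c(m_on$normalized_slope, m_off$normalized_slope))
write_table(tab, "results/photostability_metrics.csv")
write_table(data.frame(time_s = tr_on$times_s, exchange_on = tr_on$intensities,
                       exchange_off = tr_off$intensities),
            "results/photostability_traces.csv")

cat(sprintf("Exchange ON : relative change %+.2f%% over 9.6 h (no appreciable loss).\n",
            100 * m_on$relative_change))
cat(sprintf("Exchange OFF: relative change %+.1f%% (irreversible bleaching control).\n",
            100 * m_off$relative_change))
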