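#!/usr/bin/env Rscript
# Stage 3 — hyperspectral excitation-scan contrast mapping.
# Simulates a gel/buffer boundary scene (excitation 500-566 nm in 2 nm
# steps, detection 575-630 nm), extracts ROI mean excitation spectra, and
# maps the per-pixel peak excitation wavelength (binning = 2).

suppressMessages(library(glycoprobe))
dir.create("results", showWarnings = FALSE)

n <- 64
gel <- matrix(FALSE, n, n); gel[, (n / 2 + 1):n] <- TRUE
scene <- scene_spec(c(n, n), list(gel = gel, buffer = !gel),
                    c(gel = 0.9, buffer = 0), noise_sd_frac = 0.05, seed = 7)
stack <- simulate_hyperspectral(scene)

roi_gel <- roi_mean_spectrum(stack, gel)
roi_buf <- roi_mean_spectrum(stack, !gel)
write_table(data.frame(wavelength_nm = roi_gel$wavelengths_nm,
                       gel = roi_gel$values, buffer = roi_buf$values),
            "results/spectral_roi_spectra.csv")

pm <- spectral_peak_map(stack, binning = 2)
truth <- attr(stack, "truth")$peak_nm[seq(1, n, 2), seq(1, n, 2)]
acc <- mean(abs(pm$peak_nm - truth) <= 2)
write_table(data.frame(row = as.vector(row(pm$peak_nm)),
                       col = as.vector(col(pm$peak_nm)),
                       peak_nm = as.vector(pm$peak_nm)),
            "results/spectral_peak_map.csv")

peak_gel <- roi_gel$wavelengths_nm[which.max(roi_gel$values)]
peak_buf <- roi_buf$wavelengths_nm[which.max(roi_buf$values)]
cat(sprintf("ROI excitation maxima: gel %d nm, buffer %d nm (red shift %d nm).\n",
            peak_gel, peak_buf, peak_gel - peak_buf))
cat(sprintf("Peak map at 5%% noise, 2x2 binning: %.1f%% of pixels within one\n",
            100 * acc))
cat("grid step (2 nm) of the noiseless ground truth.\n")
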