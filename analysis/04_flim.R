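#!/usr/bin/env Rscript
# Stage 4 — FLIM phasor population gating.
# Simulates a two-population lifetime scene (2 ns free dye, 3.5 ns bound dye
# at an 80 MHz repetition rate, 5000 photons/pixel), transforms per-pixel
# decays to phasor space, and gates the two populations.

suppressMessages(library(glycoprobe))
dir.create("results", showWarnings = FALSE)

n <- 32
half <- matrix(FALSE, n, n); half[, (n / 2 + 1):n] <- TRUE
scene <- scene_spec(c(n, n), list(bound = half, free = !half),
                    c(bound = 1, free = 0), seed = 5)
fl <- simulate_flim(scene, photons_per_pixel = 5000)
pimg <- phasor_image(fl$stack, fl$rep_rate_hz)

w <- 2 * pi * fl$rep_rate_hz
p_free <- phasor_of_lifetime(2, w)
p_bound <- phasor_of_lifetime(3.5, w)
in_free <- gate_pixels(pimg, phasor_gate(p_free$g, p_free$s, 0.05))
in_bound <- gate_pixels(pimg, phasor_gate(p_bound$g, p_bound$s, 0.05))
correct <- (half & in_bound & !in_free) | (!half & in_free & !in_bound)

write_table(data.frame(g = as.vector(pimg$g), s = as.vector(pimg$s),
                       bound_truth = as.vector(half),
                       gated_bound = as.vector(in_bound),
                       gated_free = as.vector(in_free)),
            "results/flim_phasors.csv")
env <- result_envelope("flim", config = list(
  tau_free_ns = 2, tau_bound_ns = 3.5, rep_rate_hz = fl$rep_rate_hz,
  photons_per_pixel = 5000, gate_radius = 0.05),
  seed = scene$seed, outputs = list(
    phasor_free = p_free, phasor_bound = p_bound,
    gating_accuracy = mean(correct)), timestamp = FALSE)
write_envelope(env, "results/flim_summary.json")

cat(sprintf("Pure-lifetime phasors: free (g=%.3f, s=%.3f), bound (g=%.3f, s=%.3f).\n",
            p_free$g, p_free$s, p_bound$g, p_bound$s))
cat(sprintf("Circular gates of radius 0.05 assign %.1f%% of pixels correctly.\n",
            100 * mean(correct)))
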