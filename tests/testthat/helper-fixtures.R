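# Shared fixtures, built in code at test time.

# Paper-grade rate constants used throughout the kinetics tests.
KON_REF <- 12.8        # M^-1 s^-1
KOFF_REF <- 6.77e-4    # s^-1

# A small two-region scene: left half "buffer" (unbound), right half "gel".
two_region_scene <- function(n = 64, fraction_gel = 0.9, noise = 0.05,
                             seed = 7) {
  gel <- matrix(FALSE, n, n); gel[, (n / 2 + 1):n] <- TRUE
  scene_spec(c(n, n), list(gel = gel, buffer = !gel),
             c(gel = fraction_gel, buffer = 0),
             noise_sd_frac = noise, seed = seed)
}

# A flat-topped triangular spectrum for quick interpolation checks.
ramp_spectrum <- function(kind = "emission") {
  spectrum(seq(500, 600, by = 10), c(0:5, 4:0), kind = kind)
}
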