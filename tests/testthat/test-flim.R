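OMEGA80 <- 2 * pi * 8e7   # rad/s at an 80 MHz repetition rate

test_that("analytic phasors sit on the universal semicircle", {
  expect_equal(unlist(phasor_of_lifetime(0, OMEGA80)), c(g = 1, s = 0))
  far <- phasor_of_lifetime(1e6, OMEGA80)
  expect_lt(abs(far$g), 1e-5); expect_lt(abs(far$s), 1e-2)
  p2 <- phasor_of_lifetime(2, OMEGA80)
  expect_equal(p2$g, 0.4974, tolerance = 1e-4)
  expect_equal(p2$s, 0.5000, tolerance = 1e-4)
  taus <- seq(0, 25, by = 0.1)
  ph <- phasor_of_lifetime(taus, OMEGA80)
  expect_lt(max(abs(ph$g^2 + ph$s^2 - ph$g)), 1e-12)
  expect_error(phasor_of_lifetime(-1, OMEGA80), "nonnegative")
})

test_that("decay-histogram phasors match the closed form", {
  for (tau in c(2, 3.5)) {
    pr <- glycoprobe:::wrapped_exp_probs(tau, 4096, 12.5)
    pd <- phasor_from_decay(decay_histogram(pr * 1e6, 8e7))
    pc <- phasor_of_lifetime(tau, OMEGA80)
    expect_equal(pd$g, pc$g, tolerance = 1e-3)
    expect_equal(pd$s, pc$s, tolerance = 1e-3)
    expect_lt(abs(pd$g^2 + pd$s^2 - pd$g), 1e-3)
  }
  # a delta decay in the first of 4096 bins is (~1, ~0)
  cts <- c(1000, rep(0, 4095))
  pd <- phasor_from_decay(decay_histogram(cts, 8e7))
  expect_equal(pd$g, 1, tolerance = 1e-5)
  expect_equal(pd$s, 0, tolerance = 1e-2)
  expect_error(phasor_from_decay(decay_histogram(rep(0, 16), 8e7)),
               "zero total counts")
})

test_that("mixture phasors lie on the segment between the pure phasors", {
  p_u <- glycoprobe:::wrapped_exp_probs(2, 4096, 12.5)
  p_b <- glycoprobe:::wrapped_exp_probs(3.5, 4096, 12.5)
  pu <- phasor_from_decay(decay_histogram(p_u, 8e7))
  pb <- phasor_from_decay(decay_histogram(p_b, 8e7))
  for (f in c(0.11, 0.3, 0.5, 0.77, 0.94)) {
    pm <- phasor_from_decay(decay_histogram(f * p_b + (1 - f) * p_u, 8e7))
    expect_equal(pm$g, f * pb$g + (1 - f) * pu$g, tolerance = 1e-3)
    expect_equal(pm$s, f * pb$s + (1 - f) * pu$s, tolerance = 1e-3)
  }
})

test_that("phasor transform is invariant to uniform count scaling", {
  pr <- glycoprobe:::wrapped_exp_probs(3.5, 256, 12.5)
  p1 <- phasor_from_decay(decay_histogram(pr * 100, 8e7))
  p2 <- phasor_from_decay(decay_histogram(pr * 123456, 8e7))
  expect_equal(p1$g, p2$g); expect_equal(p1$s, p2$s)
})

test_that("two-population gating assigns nearly all pixels correctly", {
  half <- matrix(FALSE, 32, 32); half[, 17:32] <- TRUE
  sc <- scene_spec(c(32, 32), list(bound = half, free = !half),
                   c(bound = 1, free = 0), seed = 5)
  fl <- simulate_flim(sc, photons_per_pixel = 5000)
  pimg <- phasor_image(fl$stack, fl$rep_rate_hz)
  pu <- phasor_of_lifetime(2, OMEGA80)
  pb <- phasor_of_lifetime(3.5, OMEGA80)
  in_u <- gate_pixels(pimg, phasor_gate(pu$g, pu$s, 0.05))
  in_b <- gate_pixels(pimg, phasor_gate(pb$g, pb$s, 0.05))
  correct <- (half & in_b & !in_u) | (!half & in_u & !in_b)
  expect_gte(mean(correct), 0.98)
  # a gate centered on one pixel's phasor always captures it
  g1 <- phasor_gate(pimg$g[1, 1], pimg$s[1, 1], 1e-6)
  expect_true(gate_pixels(pimg, g1)[1, 1])
  # a remote gate captures nothing
  expect_false(any(gate_pixels(pimg, phasor_gate(10, 10, 0.05))))
  expect_error(phasor_gate(0.5, 0.3, 0), "positive")
})

test_that("bandpass intensity respects masks and partitions the field", {
  half <- matrix(FALSE, 16, 16); half[, 9:16] <- TRUE
  sc <- scene_spec(c(16, 16), list(bound = half, free = !half),
                   c(bound = 1, free = 0), seed = 2)
  fl <- simulate_flim(sc, photons_per_pixel = 100, n_bins = 64)
  total <- bandpass_intensity(fl$stack, matrix(TRUE, 16, 16))
  expect_true(all(total == 100))
  expect_true(all(bandpass_intensity(fl$stack, matrix(FALSE, 16, 16)) == 0))
  a <- bandpass_intensity(fl$stack, half)
  b <- bandpass_intensity(fl$stack, !half)
  expect_true(all(a + b <= total))
  expect_equal(a + b, total)   # complementary gates cover everything here
  expect_error(bandpass_intensity(fl$stack, matrix(TRUE, 4, 4)), "mask shape")
})
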