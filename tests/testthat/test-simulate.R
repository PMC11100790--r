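test_that("default dye construction honors shifts and contrast targets", {
  dye <- make_default_dye()
  au <- dye$unbound$absorbance; ab <- dye$bound$absorbance
  shift_abs <- ab$wavelengths_nm[which.max(ab$values)] -
    au$wavelengths_nm[which.max(au$values)]
  expect_equal(shift_abs, 13)
  eu <- dye$unbound$emission; eb <- dye$bound$emission
  shift_em <- eb$wavelengths_nm[which.max(eb$values)] -
    eu$wavelengths_nm[which.max(eu$values)]
  expect_equal(shift_em, 14)
  rfp <- acquisition_settings(561, c(575, Inf))
  expect_equal(model_contrast(dye, rfp), 7.3, tolerance = 1e-3)
  # target contrast 0 equalizes the integrated signals
  dye0 <- make_default_dye(target_contrast = 0)
  expect_equal(signal_at_settings(dye0, 1, rfp), signal_at_settings(dye0, 0, rfp))
  expect_error(make_default_dye(target_contrast = -1.5), "unreachable")
})

test_that("simulated timelapses are exact without noise and seeded with it", {
  tl0 <- simulate_timelapse(5e-6, noise_sd_frac = 0)
  truth <- attr(tl0, "truth")
  expect_equal(tl0$intensities,
               binding_model(tl0$times_s, truth$Imax, truth$kobs, truth$t0,
                             truth$b))
  # half rise sits at t0 + ln2/kobs
  rc <- list(kon = truth$kon, koff = truth$koff)
  t_half <- truth$t0 + time_to_fraction(rc, 5e-6, 0.5)
  half_level <- truth$b + truth$Imax / 2
  i <- findInterval(t_half, tl0$times_s)
  expect_true(tl0$intensities[i] <= half_level &&
                tl0$intensities[i + 1] >= half_level)
  expect_identical(simulate_timelapse(5e-6, seed = 12)$intensities,
                   simulate_timelapse(5e-6, seed = 12)$intensities)
  expect_error(simulate_timelapse(-1e-6), "positive")
  expect_error(simulate_timelapse(5e-6, kon = -1), "invalid rate")
})

test_that("scene-based generators are deterministic under a fixed seed", {
  sc <- two_region_scene(seed = 13)
  expect_identical(simulate_hyperspectral(sc)$data,
                   simulate_hyperspectral(sc)$data)
  expect_identical(simulate_flim(sc, n_bins = 64, photons_per_pixel = 200)$stack,
                   simulate_flim(sc, n_bins = 64, photons_per_pixel = 200)$stack)
  expect_identical(simulate_array(seed = 3)$image, simulate_array(seed = 3)$image)
  expect_identical(simulate_photostability(seed = 3)$intensities,
                   simulate_photostability(seed = 3)$intensities)
  # generators record their seed in the ground truth
  expect_equal(attr(simulate_hyperspectral(sc), "truth")$seed, 13)
})

test_that("hyperspectral scenes separate regions by grid peak", {
  sc <- two_region_scene(noise = 0)
  st <- simulate_hyperspectral(sc)
  peaks <- unique(as.vector(attr(st, "truth")$peak_nm))
  expect_length(peaks, 2)
  expect_setequal(peaks, c(548, 560))
  # fully unbound scene: one shared peak everywhere
  gel <- sc$region_masks$gel
  sc0 <- scene_spec(c(64, 64), list(gel = gel, buffer = !gel),
                    c(gel = 0, buffer = 0), noise_sd_frac = 0)
  st0 <- simulate_hyperspectral(sc0)
  expect_length(unique(as.vector(attr(st0, "truth")$peak_nm)), 1)
})

test_that("FLIM scenes cluster at the pure phasors and flag severe wrap", {
  w <- 2 * pi * 8e7
  half <- matrix(FALSE, 16, 16); half[, 9:16] <- TRUE
  sc <- scene_spec(c(16, 16), list(a = half, b = !half), c(a = 0, b = 0),
                   seed = 8)
  fl <- simulate_flim(sc, photons_per_pixel = 5000)
  pimg <- phasor_image(fl$stack, fl$rep_rate_hz)
  pu <- phasor_of_lifetime(2, w)
  expect_lt(max(abs(pimg$g - pu$g)), 0.05)
  expect_lt(max(abs(pimg$s - pu$s)), 0.05)
  expect_warning(simulate_flim(sc, tau_bound_ns = 20, photons_per_pixel = 10,
                               n_bins = 32),
                 "wraps around")
})

test_that("expected-count FLIM decays reproduce the mixture phasor", {
  f <- 0.5
  p_mix <- f * glycoprobe:::wrapped_exp_probs(3.5, 4096, 12.5) +
    (1 - f) * glycoprobe:::wrapped_exp_probs(2, 4096, 12.5)
  pm <- phasor_from_decay(decay_histogram(p_mix * 1e9, 8e7))
  w <- 2 * pi * 8e7
  pu <- phasor_of_lifetime(2, w); pb <- phasor_of_lifetime(3.5, w)
  expect_equal(pm$g, f * pb$g + (1 - f) * pu$g, tolerance = 1e-3)
  expect_equal(pm$s, f * pb$s + (1 - f) * pu$s, tolerance = 1e-3)
})

test_that("null arrays yield no detections and gradients cancel out", {
  lay <- default_array_layout()
  sim <- simulate_array(lay, effects = stats::setNames(rep(0, 100),
                                                       sprintf("G%03d", 1:100)),
                        seed = 17)
  sp <- quantify_array(sim$image, lay, normalize = FALSE)
  calls <- tapply(sp$corrected, sp$glycan, mean) >
    2 * tapply(sp$background_sd, sp$glycan, mean)
  expect_lte(mean(calls), 0.05)
  # gradient-only image: corrected signals stay near zero
  sim2 <- simulate_array(lay, effects = stats::setNames(rep(0, 100),
                                                        sprintf("G%03d", 1:100)),
                         gradient = c(0.05, 0.08), noise_sd = 2, seed = 18)
  sp2 <- quantify_array(sim2$image, lay, normalize = FALSE)
  expect_gte(mean(abs(sp2$corrected) < 0.5 * 2), 0.95)
  # one strong spot is detected
  amp <- stats::setNames(rep(0, 100), sprintf("G%03d", 1:100)); amp["G001"] <- 20
  sim3 <- simulate_array(lay, effects = amp, noise_sd = 2, seed = 19)
  sp3 <- quantify_array(sim3$image, lay, normalize = FALSE)
  g1 <- sp3[sp3$glycan == "G001", ]
  expect_true(detection_call(mean(g1$corrected), mean(g1$background_sd)))
})
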