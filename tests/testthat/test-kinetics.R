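test_that("noiseless synthetic trace is recovered to high precision", {
  tl <- simulate_timelapse(5e-6, noise_sd_frac = 0)
  truth <- attr(tl, "truth")
  fit <- suppressWarnings(fit_binding_timelapse(tl))
  expect_equal(fit$kobs, truth$kobs, tolerance = 1e-6)
  expect_equal(fit$Imax, truth$Imax, tolerance = 1e-6)
  expect_equal(fit$t0, truth$t0, tolerance = 1e-6)
  expect_equal(fit$b, truth$b, tolerance = 1e-6)
})

test_that("flat traces are rejected as not identifiable", {
  tl <- binding_timelapse(seq(0, 600, 60), rep(5, 11), 5e-6)
  expect_error(fit_binding_timelapse(tl), "not identifiable")
})

test_that("true kobs falls in the fitted 95% CI for most noisy replicates", {
  hits <- vapply(1:100, function(s) {
    tl <- simulate_timelapse(5e-6, seed = 1000 + s)   # 2% noise default
    fit <- fit_binding_timelapse(tl)
    ci <- kobs_confint(fit)
    truth <- attr(tl, "truth")
    truth$kobs >= ci[1] && truth$kobs <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("kobs is invariant to affine intensity rescaling", {
  tl <- simulate_timelapse(1e-5, seed = 3)
  f1 <- fit_binding_timelapse(tl)
  a <- 3.7; c0 <- 25
  tl2 <- binding_timelapse(tl$times_s, a * tl$intensities + c0,
                           tl$concentration_M)
  f2 <- fit_binding_timelapse(tl2)
  expect_equal(f2$kobs, f1$kobs, tolerance = 1e-6)
  expect_equal(f2$Imax, a * f1$Imax, tolerance = 1e-6)
  expect_equal(f2$b, a * f1$b + c0, tolerance = 1e-6)
})

test_that("rate line through exact points recovers kon and koff", {
  conc <- c(2.5, 5, 10, 20) * 1e-6
  kobs <- KON_REF * conc + KOFF_REF
  rc <- fit_rate_line(conc, kobs)
  expect_equal(rc$kon, KON_REF, tolerance = 1e-12)
  expect_equal(rc$koff, KOFF_REF, tolerance = 1e-12)
  expect_equal(rc$KD, KOFF_REF / KON_REF, tolerance = 1e-12)
  # two exact points give the interpolating line
  rc2 <- fit_rate_line(conc[1:2], kobs[1:2])
  expect_equal(rc2$kon, KON_REF, tolerance = 1e-12)
  expect_error(fit_rate_line(rep(5e-6, 3), kobs[1:3]), "distinct")
})

test_that("nonpositive intercept flags KD as unavailable", {
  conc <- c(1, 2, 4) * 1e-6
  kobs <- 10 * conc - 1e-5   # negative intercept
  expect_warning(rc <- fit_rate_line(conc, kobs), "KD not available")
  expect_true(is.na(rc$KD))
})

test_that("KD identity holds bit for bit and has correct units", {
  expect_identical(dissociation_constant(12.8, 6.77e-4), 6.77e-4 / 12.8)
  expect_equal(dissociation_constant(12.8, 6.77e-4), 5.289e-5,
               tolerance = 1e-4)
  expect_identical(dissociation_constant(1, 1), 1)
  expect_identical(dissociation_constant(2, 0), 0)
  expect_error(dissociation_constant(0, 1), "kon")
  rc <- fit_rate_line(c(1e-6, 2e-6, 4e-6), c(1.5e-3, 2.5e-3, 4.5e-3))
  expect_identical(rc$KD, rc$koff / rc$kon)
})

test_that("kobs prediction and time-to-fraction follow the closed forms", {
  rc <- list(kon = KON_REF, koff = KOFF_REF)
  expect_equal(predict_kobs(rc, 0), KOFF_REF)
  kobs5 <- KON_REF * 5e-6 + KOFF_REF   # 7.41e-4 s^-1
  expect_equal(predict_kobs(rc, 5e-6), 7.41e-4, tolerance = 1e-12)
  expect_error(predict_kobs(rc, -1e-6), "nonnegative")
  expect_equal(time_to_fraction(rc, 5e-6, 0), 0)
  # half rise and 90% rise at 5 uM with the reference constants
  expect_equal(time_to_fraction(rc, 5e-6, 0.5), log(2) / kobs5)
  expect_equal(time_to_fraction(rc, 5e-6, 0.9), log(10) / kobs5)
  # closed-form identity: t50 * kobs = ln 2 exactly
  for (C in c(1e-6, 5e-6, 2e-5))
    expect_equal(time_to_fraction(rc, C, 0.5) * predict_kobs(rc, C), log(2))
  expect_error(time_to_fraction(rc, 5e-6, 1), "fraction")
})

test_that("noiseless two-stage pipeline recovers the generator constants", {
  tls <- simulate_kinetics_experiment(noise_sd_frac = 0)
  pp <- suppressWarnings(kinetics_pipeline(tls))
  expect_equal(pp$rates$kon, KON_REF, tolerance = 1e-4)
  expect_equal(pp$rates$koff, KOFF_REF, tolerance = 1e-4)
  expect_equal(pp$rates$KD, KOFF_REF / KON_REF, tolerance = 1e-4)
})

test_that("timelapse validation enforces the sampling contract", {
  expect_error(binding_timelapse(1:5, 1:5, 5e-6), "at least 8")
  expect_error(binding_timelapse(c(1:7, 7), rnorm(8), 5e-6), "increasing")
  expect_error(binding_timelapse(1:8, rnorm(8), 0), "positive")
})
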