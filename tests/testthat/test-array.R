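test_that("spot quantification handles uniform fields and synthetic disks", {
  img <- matrix(7.5, 40, 40)
  q <- quantify_spot(img, c(20, 20), 4, c(6, 9))
  expect_equal(q$raw, 7.5)
  expect_equal(q$background, 7.5)
  expect_equal(q$corrected, 0)
  expect_equal(q$background_sd, 0)
  # disk of +50 over a flat background of 100
  img2 <- matrix(100, 40, 40)
  rr <- outer((1:40 - 20)^2, (1:40 - 20)^2, `+`)
  img2[rr <= 16] <- 150
  q2 <- quantify_spot(img2, c(20, 20), 4, c(6, 9))
  expect_equal(q2$corrected, 50, tolerance = 0.02)
  # additive offsets cancel in the corrected signal
  q3 <- quantify_spot(img2 + 31.4, c(20, 20), 4, c(6, 9))
  expect_equal(q3$corrected, q2$corrected)
  expect_error(quantify_spot(img, c(2, 2), 4, c(6, 9)), "outside")
})

test_that("within-array normalization is scale invariant", {
  x <- c(10, 20, 5, 1, 0.5)
  expect_equal(normalize_within_array(x * 8), normalize_within_array(x))
  expect_true(all(normalize_within_array(rep(4, 6)) == 1))
  expect_error(normalize_within_array(c(-1, -2)), "nonpositive")
})

test_that("normalized values agree across arrays with different gains", {
  sims <- lapply(c(0.8, 1.0, 1.25), function(gain) {
    sim <- simulate_array(seed = 21)   # identical scene
    sim$image <- sim$image * gain
    quantify_array(sim$image, sim$layout)
  })
  per_glycan <- sapply(sims, function(sp)
    tapply(sp$normalized, sp$glycan, mean))
  cv <- apply(per_glycan, 1, function(v) stats::sd(v) / abs(mean(v)))
  # identical scenes, so normalization must cancel the gain exactly;
  # only binder glycans (non-tiny means) are meaningful for a CV
  binders <- rowMeans(per_glycan) > 0.1
  expect_lt(max(cv[binders]), 0.05)
})

test_that("detection calls use a strict 2-sigma rule", {
  expect_true(detection_call(3, 1))
  expect_false(detection_call(1, 1))
  expect_false(detection_call(2, 1))   # boundary is strict
  expect_error(detection_call(1, -0.1), "nonnegative")
})

test_that("Dunnett-adjusted p-values behave at the extremes", {
  set.seed(1)
  ctrl <- rnorm(8)
  near <- ctrl[1:4] + 1e-3 * rnorm(4)
  grps <- c(list(near), lapply(1:99, function(i) rnorm(4)))
  dn <- dunnett_vs_control(grps, ctrl, n_mc = 2e4)
  expect_gt(dn$p_adj[1], 0.9)
  grps2 <- lapply(1:100, function(i) rnorm(4))
  grps2[[7]] <- grps2[[7]] + 10
  dn2 <- dunnett_vs_control(grps2, rnorm(8), n_mc = 2e4)
  expect_lt(dn2$p_adj[7], 0.001)
  expect_true(all(dn2$p_adj >= dn2$p_raw - 1e-12))
  # adjusted p monotone in |t|
  ord <- order(abs(dn2$t))
  expect_true(all(diff(dn2$p_adj[ord]) <= 1e-12))
  expect_error(dunnett_vs_control(list(1), rnorm(4)), "at least 2")
})

test_that("MC Welch-Dunnett agrees with the classic Dunnett on equal variances", {
  skip_if_not_installed("multcomp")
  set.seed(42)
  k <- 6; n <- 25
  mus <- c(0, 0.2, 0.4, 0.6, 0.8, 0)
  grps <- lapply(seq_len(k), function(i) rnorm(n, mean = mus[i]))
  ctrl <- rnorm(n)
  dn <- dunnett_vs_control(grps, ctrl, n_mc = 1e5, seed = 7)
  df <- data.frame(y = c(ctrl, unlist(grps)),
                   g = factor(rep(0:k, rep(n, k + 1))))
  mc <- summary(multcomp::glht(stats::aov(y ~ g, df),
                               linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(dn$p_adj, as.numeric(mc$test$pvalues), tolerance = 0.05)
})

test_that("full array analysis separates binders from non-binders", {
  sim <- simulate_array(seed = 11)
  res <- analyze_array(sim$image, sim$layout, n_mc = 2e4, seed = 42)
  g <- merge(res$glycans, sim$truth, by = "glycan")
  expect_gte(sum(g$detected & g$binder), 95)
  expect_lte(sum((g$detected | g$significant) & !g$binder), 1)
  expect_true(all(g$p_adj >= 0 & g$p_adj <= 1))
})

test_that("array simulation validates layout geometry", {
  lay <- default_array_layout(pitch = 6, spot_radius = 4, annulus_radii = c(5, 6))
  expect_error(simulate_array(lay), "overlapping")
  expect_error(array_layout(default_array_layout()$centers, 4, c(3, 9)),
               "annulus inner")
})
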