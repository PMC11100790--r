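#' Default synthetic two-state dye model
#'
#' Builds a Gaussian-band fluorogenic dye whose bound state is red-shifted by
#' `abs_shift_nm` in absorbance and `em_shift_nm` in emission, and whose
#' bound emission amplitude is calibrated in closed form so that the
#' fluorogenic contrast at the calibration settings (561 nm excitation,
#' 575 nm longpass detection) equals `target_contrast` exactly. Absorbance
#' amplitudes follow Beer-Lambert at the reference condition (5 uM dye, 1 cm
#' path).
#'
#' @param target_contrast desired delta-F/F at the calibration settings
#'   (default 7.3); must exceed -1.
#' @param abs_peak_unbound_nm,em_peak_unbound_nm unbound band centers (nm).
#' @param abs_shift_nm,em_shift_nm bound-state red shifts (nm).
#' @param abs_sd_nm,em_sd_nm Gaussian band widths (nm).
#' @param shoulder_frac,shoulder_offset_nm,shoulder_sd_nm amplitude fraction,
#'   blue offset and width of a secondary absorbance shoulder, giving the
#'   bands the blue tail through which a 488 nm line still excites the dye.
#' @param epsilon_unbound,epsilon_bound peak molar extinctions (M^-1 cm^-1).
#' @param phi_unbound,phi_bound quantum yields.
#' @param ref_concentration_M reference concentration for the stored
#'   absorbance spectra (1 cm path).
#' @param grid_nm wavelength grid for both spectra.
#' @param calibration an [acquisition_settings()] at which the contrast is
#'   pinned.
#' @return a [two_state_dye()] whose [model_contrast()] at `calibration`
#'   equals `target_contrast`.
#' @export
make_default_dye <- function(target_contrast = 7.3,
                             abs_peak_unbound_nm = 548,
                             em_peak_unbound_nm = 572,
                             abs_shift_nm = 13, em_shift_nm = 14,
                             abs_sd_nm = 6, em_sd_nm = 15,
                             shoulder_frac = 0.1, shoulder_offset_nm = 55,
                             shoulder_sd_nm = 25,
                             epsilon_unbound = 8e4, epsilon_bound = 1e5,
                             phi_unbound = 0.60, phi_bound = 0.85,
                             ref_concentration_M = 5e-6,
                             grid_nm = seq(450, 700, by = 0.5),
                             calibration = acquisition_settings(561, c(575, Inf))) {
  if (target_contrast <= -1)
    stop("unreachable target contrast: delta-F/F must exceed -1")
  gauss <- function(center, sd) exp(-0.5 * ((grid_nm - center) / sd)^2)
  abs_band <- function(center)
    gauss(center, abs_sd_nm) +
      shoulder_frac * gauss(center - shoulder_offset_nm, shoulder_sd_nm)
  a_u <- epsilon_unbound * ref_concentration_M * abs_band(abs_peak_unbound_nm)
  a_b <- epsilon_bound * ref_concentration_M *
    abs_band(abs_peak_unbound_nm + abs_shift_nm)
  e_u <- gauss(em_peak_unbound_nm, em_sd_nm)
  e_b <- gauss(em_peak_unbound_nm + em_shift_nm, em_sd_nm)
  unbound <- dye_state(epsilon_unbound, phi_unbound,
                       spectrum(grid_nm, a_u, "absorbance"),
                       spectrum(grid_nm, e_u, "emission"))
  bound <- dye_state(epsilon_bound, phi_bound,
                     spectrum(grid_nm, a_b, "absorbance"),
                     spectrum(grid_nm, e_b, "emission"))
  s_u <- state_signal(unbound, calibration)
  s_b_unit <- state_signal(bound, calibration)
  if (s_u <= 0 || s_b_unit <= 0)
    stop("unreachable target contrast: no signal in the calibration band")
  kappa <- (1 + target_contrast) * s_u / s_b_unit
  bound$emission <- spectrum(grid_nm, e_b * kappa, "emission")
  two_state_dye(unbound, bound)
}

#' Simulate a binding timelapse
#'
#' Noiseless mean from the saturation model with
#' `kobs = kon * concentration + koff`, plus additive Gaussian noise of
#' standard deviation `noise_sd_frac * Imax`. Ground truth is attached as
#' attribute `"truth"`.
#'
#' @param concentration_M dye concentration (molar), `> 0`.
#' @param kon association rate (M^-1 s^-1, default 12.8).
#' @param koff dissociation rate (s^-1, default 6.77e-4).
#' @param times_s sampling times; default 181 frames over 3 h at 1 frame/min.
#' @param Imax,t0,b model amplitude, onset delay (s) and background.
#' @param noise_sd_frac Gaussian noise SD as a fraction of `Imax`.
#' @param seed RNG seed.
#' @return a [binding_timelapse()] with a `truth` attribute.
#' @export
simulate_timelapse <- function(concentration_M, kon = 12.8, koff = 6.77e-4,
                               times_s = seq(0, 10800, by = 60),
                               Imax = 100, t0 = 60, b = 10,
                               noise_sd_frac = 0.02, seed = 1) {
  if (kon <= 0 || koff < 0) stop("invalid rate constants")
  if (concentration_M <= 0) stop("concentration must be positive")
  kobs <- kon * concentration_M + koff
  mu <- binding_model(times_s, Imax, kobs, t0, b)
  I <- if (noise_sd_frac > 0)
    with_seed(seed, mu + stats::rnorm(length(mu), sd = noise_sd_frac * Imax))
  else mu
  tl <- binding_timelapse(times_s, I, concentration_M)
  attr(tl, "truth") <- list(kon = kon, koff = koff, kobs = kobs, Imax = Imax,
                            t0 = t0, b = b, seed = seed,
                            noise_sd_frac = noise_sd_frac)
  tl
}

#' Simulate a multi-concentration kinetics experiment
#'
#' One timelapse per concentration, with per-trace seeds derived from `seed`.
#'
#' @param concentrations_M dye concentrations; default
#'   `{2.5, 5, 10, 20}` uM.
#' @param seed base RNG seed.
#' @param ... further arguments passed to [simulate_timelapse()].
#' @return list of [binding_timelapse()] objects.
#' @export
simulate_kinetics_experiment <- function(concentrations_M = c(2.5, 5, 10, 20) * 1e-6,
                                         seed = 1, ...) {
  lapply(seq_along(concentrations_M), function(i)
    simulate_timelapse(concentrations_M[i], seed = seed * 100 + i, ...))
}

#' Specify a synthetic imaging scene
#'
#' Disjoint labeled regions (e.g. gel versus surrounding buffer) over an
#' image plane, each with its own bound fraction and brightness.
#'
#' @param shape `c(rows, cols)`.
#' @param region_masks named list of logical matrices (pairwise disjoint).
#' @param fraction_bound named numeric in `[0, 1]`, one per region.
#' @param brightness named numeric scaling per region (default 1).
#' @param noise_sd_frac Gaussian noise SD as a fraction of the local
#'   noiseless signal.
#' @param seed RNG seed, recorded in all outputs.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape, region_masks, fraction_bound,
                       brightness = NULL, noise_sd_frac = 0.02, seed = 1) {
  stopifnot(length(shape) == 2L, is.list(region_masks))
  regions <- names(region_masks)
  if (is.null(regions) || any(regions == ""))
    stop("region masks must be named")
  if (is.null(brightness)) brightness <- stats::setNames(rep(1, length(regions)), regions)
  cover <- Reduce(`+`, lapply(region_masks, function(m) {
    if (!identical(dim(m), as.integer(shape))) stop("mask shape mismatch")
    m * 1
  }))
  if (any(cover > 1)) stop("region masks must be disjoint")
  fb <- fraction_bound[regions]
  if (any(is.na(fb)) || any(fb < 0 | fb > 1))
    stop("fraction_bound must be given per region, in [0, 1]")
  structure(list(shape = as.integer(shape), region_masks = region_masks,
                 fraction_bound = fb, brightness = brightness[regions],
                 noise_sd_frac = noise_sd_frac, seed = seed),
            class = "scene_spec")
}

#' Simulate an excitation-scan image cube
#'
#' Each pixel's excitation spectrum is the two-state mixture spectrum at its
#' region's bound fraction (evaluated through the photophysics model at every
#' grid wavelength), scaled by region brightness, with multiplicative
#' Gaussian noise (SD = `noise_sd_frac` x the local noiseless value,
#' truncated at zero). The noiseless per-pixel grid peak is stored as ground
#' truth.
#'
#' @param scene a [scene_spec()].
#' @param dye a [two_state_dye()] (default [make_default_dye()]).
#' @param excitation_grid_nm excitation wavelengths (default 500-566 nm in
#'   2 nm steps).
#' @param emission_band detection band (default 575-630 nm).
#' @return a [hyperspectral_stack()] with attribute `truth`: list with
#'   `peak_nm` matrix (noiseless grid argmax, `NA` outside all regions) and
#'   the scene seed.
#' @export
simulate_hyperspectral <- function(scene, dye = make_default_dye(),
                                   excitation_grid_nm = seq(500, 566, by = 2),
                                   emission_band = c(575, 630)) {
  stopifnot(inherits(scene, "scene_spec"), inherits(dye, "two_state_dye"))
  nwl <- length(excitation_grid_nm)
  s_b <- vapply(excitation_grid_nm, function(wl)
    state_signal(dye$bound, acquisition_settings(wl, emission_band)), numeric(1))
  s_u <- vapply(excitation_grid_nm, function(wl)
    state_signal(dye$unbound, acquisition_settings(wl, emission_band)), numeric(1))
  shape <- scene$shape
  clean <- array(0, dim = c(nwl, shape))
  truth_peak <- matrix(NA_real_, shape[1], shape[2])
  for (rg in names(scene$region_masks)) {
    f <- scene$fraction_bound[[rg]]
    spec <- (f * s_b + (1 - f) * s_u) * scene$brightness[[rg]]
    m <- scene$region_masks[[rg]]
    idx <- which(m)
    for (i in seq_len(nwl)) {
      plane <- clean[i, , ]
      plane[idx] <- spec[i]
      clean[i, , ] <- plane
    }
    truth_peak[idx] <- excitation_grid_nm[which.max(spec)]
  }
  data <- if (scene$noise_sd_frac > 0) {
    noisy <- clean + with_seed(scene$seed,
      array(stats::rnorm(length(clean), sd = scene$noise_sd_frac * clean),
            dim = dim(clean)))
    noisy[noisy < 0] <- 0
    noisy
  } else clean
  st <- hyperspectral_stack(excitation_grid_nm, data, emission_band)
  attr(st, "truth") <- list(peak_nm = truth_peak, seed = scene$seed)
  st
}

# Bin probabilities of a mono-exponential decay wrapped over one laser period.
wrapped_exp_probs <- function(tau_ns, n_bins, period_ns) {
  e <- seq(0, period_ns, length.out = n_bins + 1L)
  (exp(-utils::head(e, -1) / tau_ns) - exp(-utils::tail(e, -1) / tau_ns)) /
    (1 - exp(-period_ns / tau_ns))
}

#' Simulate a FLIM decay stack
#'
#' Every pixel draws `photons_per_pixel` photon arrival times from the
#' count-weighted two-exponential mixture of its region (bound lifetime
#' weighted by the region's bound fraction), wrapped over the laser period,
#' via a multinomial over time bins. Pixels outside all regions stay empty.
#'
#' @param scene a [scene_spec()] (its `fraction_bound` is the photon
#'   fraction from the bound-lifetime population).
#' @param tau_unbound_ns,tau_bound_ns lifetimes (default 2 and 3.5 ns).
#' @param rep_rate_hz laser repetition rate (default 80 MHz).
#' @param photons_per_pixel expected photons per pixel.
#' @param n_bins number of uniform time bins over the period.
#' @return list with `stack` (3-D array `(bin, row, col)`), `rep_rate_hz`,
#'   and `truth` (per-pixel bound fraction, lifetimes, seed).
#' @export
simulate_flim <- function(scene, tau_unbound_ns = 2, tau_bound_ns = 3.5,
                          rep_rate_hz = 8e7, photons_per_pixel = 5000,
                          n_bins = 256) {
  stopifnot(inherits(scene, "scene_spec"))
  if (tau_unbound_ns <= 0 || tau_bound_ns <= 0) stop("lifetimes must be positive")
  if (photons_per_pixel < 1) stop("need at least one photon per pixel")
  period_ns <- 1e9 / rep_rate_hz
  if (max(tau_unbound_ns, tau_bound_ns) > period_ns)
    warning("lifetime exceeds the laser period: decay wraps around severely")
  p_u <- wrapped_exp_probs(tau_unbound_ns, n_bins, period_ns)
  p_b <- wrapped_exp_probs(tau_bound_ns, n_bins, period_ns)
  shape <- scene$shape
  stack <- array(0, dim = c(n_bins, shape))
  fr_truth <- matrix(NA_real_, shape[1], shape[2])
  with_seed(scene$seed, {
    for (rg in names(scene$region_masks)) {
      f <- scene$fraction_bound[[rg]]
      idx <- which(scene$region_masks[[rg]])
      if (!length(idx)) next
      draws <- stats::rmultinom(length(idx), size = photons_per_pixel,
                                prob = f * p_b + (1 - f) * p_u)
      flat <- matrix(stack, nrow = n_bins)
      flat[, idx] <- draws
      stack <- array(flat, dim = c(n_bins, shape))
      fr_truth[idx] <- f
    }
  })
  list(stack = stack, rep_rate_hz = rep_rate_hz,
       truth = list(fraction_bound = fr_truth,
                    tau_unbound_ns = tau_unbound_ns,
                    tau_bound_ns = tau_bound_ns, seed = scene$seed))
}

#' Simulate a glycan-array image
#'
#' Disk spots of per-glycan amplitude over a background with an optional
#' linear gradient and additive Gaussian noise. By default 98 of the 100
#' glycans are binders with amplitudes drawn (seeded) between 5 and 25 times
#' the noise SD, the last two glycans and all control spots have zero
#' amplitude — the structure of a broad-specificity probe on a commercial
#' 100-glycan array.
#'
#' @param layout an [array_layout()] with an `image_dim` element (see
#'   [default_array_layout()]).
#' @param effects optional named amplitude per glycan (a.u.); `NULL` draws
#'   the default described above.
#' @param background constant background level.
#' @param gradient `c(per_row, per_col)` linear background slope.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed (amplitudes and noise).
#' @return list with `image`, `truth` (data.frame glycan/amplitude/binder),
#'   `layout`, `seed`.
#' @export
simulate_array <- function(layout = default_array_layout(), effects = NULL,
                           background = 100, gradient = c(0, 0),
                           noise_sd = 2, seed = 1) {
  stopifnot(inherits(layout, "array_layout"))
  if (is.null(layout$image_dim)) stop("layout lacks image dimensions")
  cen <- layout$centers
  dmat <- as.matrix(stats::dist(cen[, c("row", "col")]))
  diag(dmat) <- Inf
  if (min(dmat) < 2 * layout$spot_radius) stop("layout has overlapping spots")
  glycans <- setdiff(unique(cen$glycan), "control")
  with_seed(seed, {
    if (is.null(effects)) {
      amp <- stats::setNames(rep(0, length(glycans)), glycans)
      n_bind <- max(0L, length(glycans) - 2L)
      if (n_bind > 0)
        amp[seq_len(n_bind)] <- stats::runif(n_bind, 5, 25) * noise_sd
      effects <- amp
    }
    nr <- layout$image_dim[1]; nc <- layout$image_dim[2]
    img <- background +
      outer((seq_len(nr) - 1) * gradient[1], rep(1, nc)) +
      outer(rep(1, nr), (seq_len(nc) - 1) * gradient[2])
    r <- layout$spot_radius
    for (i in seq_len(nrow(cen))) {
      a <- if (cen$glycan[i] == "control") 0 else effects[[cen$glycan[i]]]
      if (a == 0) next
      rr <- (cen$row[i] - r):(cen$row[i] + r)
      cc <- (cen$col[i] - r):(cen$col[i] + r)
      d2 <- outer((rr - cen$row[i])^2, (cc - cen$col[i])^2, `+`)
      img[rr, cc] <- img[rr, cc] + a * (d2 <= r^2)
    }
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = noise_sd)
    truth <- data.frame(glycan = glycans,
                        amplitude = unname(effects[glycans]),
                        binder = unname(effects[glycans]) > 0)
    list(image = img, truth = truth, layout = layout, seed = seed)
  })
}

#' Simulate a long photostability trace
#'
#' With exchange disabled the bound dye bleaches irreversibly:
#' `I(t) = I0 * exp(-kb * t)`. With exchange enabled, a discrete-time
#' two-pool model is used: each frame a fraction `1 - exp(-kb * dt)` of the
#' bound dye photobleaches and is instantaneously replaced from a free pool
#' `free_pool_excess` times the bound population; bleached molecules dilute
#' into the joint pool, so the unbleached fraction decays by
#' `(1 - q / (1 + excess))` per frame — the mechanism by which excess free
#' dye buys apparent photostability.
#'
#' @param duration_s total duration (default 9.6 h).
#' @param frame_interval_s frame interval (default 60 s).
#' @param kb bound-state photobleaching rate (1/s).
#' @param exchange logical: free/bound exchange on?
#' @param free_pool_excess free pool size relative to the bound population.
#' @param I0 initial intensity.
#' @param noise_sd_frac additive Gaussian noise SD as a fraction of `I0`
#'   (the trace is an ROI mean, so its noise is well below per-pixel noise).
#' @param seed RNG seed.
#' @return a [roi_trace()] with a `truth` attribute (model parameters and
#'   the noiseless final/initial ratio).
#' @export
simulate_photostability <- function(duration_s = 9.6 * 3600,
                                    frame_interval_s = 60, kb = 1e-5,
                                    exchange = TRUE, free_pool_excess = 100,
                                    I0 = 100, noise_sd_frac = 0.005, seed = 1) {
  if (kb < 0 || free_pool_excess < 0) stop("rates and pool sizes must be nonnegative")
  times <- seq(0, duration_s, by = frame_interval_s)
  m <- seq_along(times) - 1L
  u <- if (!exchange || kb == 0) {
    exp(-kb * times)
  } else {
    q <- 1 - exp(-kb * frame_interval_s)
    (1 - q / (1 + free_pool_excess))^m
  }
  mu <- I0 * u
  I <- if (noise_sd_frac > 0)
    with_seed(seed, mu + stats::rnorm(length(mu), sd = noise_sd_frac * I0))
  else mu
  tr <- roi_trace(times, I, roi = if (exchange) "exchange_on" else "exchange_off")
  attr(tr, "truth") <- list(kb = kb, exchange = exchange,
                            free_pool_excess = free_pool_excess,
                            final_fraction = u[length(u)], seed = seed)
  tr
}

#' Simulate a two-region photostability timelapse stack
#'
#' Small image stack whose regions follow [simulate_photostability()] traces,
#' for exercising [roi_traces()] end to end.
#'
#' @param scene a [scene_spec()]; each region gets an independent trace.
#' @param ... arguments forwarded to [simulate_photostability()] (per-region
#'   seeds derive from the scene seed).
#' @return list with `stack` (frame, row, col), `frame_interval_s`, and
#'   `truth` traces per region.
#' @export
simulate_photostability_stack <- function(scene, ...) {
  stopifnot(inherits(scene, "scene_spec"))
  args <- list(...)
  args$noise_sd_frac <- NULL   # stack noise comes from the scene spec
  fi <- if (!is.null(args$frame_interval_s)) args$frame_interval_s else 60
  traces <- lapply(seq_along(scene$region_masks), function(i) {
    do.call(simulate_photostability,
            c(list(seed = scene$seed * 10 + i, noise_sd_frac = 0), args))
  })
  names(traces) <- names(scene$region_masks)
  n <- length(traces[[1]]$times_s)
  stack <- array(0, dim = c(n, scene$shape))
  flat <- matrix(stack, nrow = n)
  for (rg in names(traces)) {
    idx <- which(scene$region_masks[[rg]])
    flat[, idx] <- traces[[rg]]$intensities *
      scene$brightness[[rg]]
  }
  stack <- array(flat, dim = c(n, scene$shape))
  if (scene$noise_sd_frac > 0) {
    stack <- stack + with_seed(scene$seed,
      array(stats::rnorm(length(stack), sd = scene$noise_sd_frac * stack),
            dim = dim(stack)))
    stack[stack < 0] <- 0
  }
  list(stack = stack, frame_interval_s = fi, truth = traces)
}
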