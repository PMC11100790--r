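#' A binding timelapse
#'
#' Mean field-of-view intensity versus time for one dye concentration, the
#' raw material of the pseudo-first-order kinetics analysis.
#'
#' @param times_s strictly increasing, nonnegative times (seconds), `>= 8`.
#' @param intensities mean intensities (arbitrary units), same length.
#' @param concentration_M final dye concentration (molar), `> 0`.
#' @return An object of class `binding_timelapse`.
#' @export
binding_timelapse <- function(times_s, intensities, concentration_M) {
  times_s <- as.numeric(times_s); intensities <- as.numeric(intensities)
  if (length(times_s) != length(intensities))
    stop("times and intensities must have the same length")
  if (length(times_s) < 8L) stop("need at least 8 time points")
  if (any(times_s < 0) || any(diff(times_s) <= 0))
    stop("times must be nonnegative and strictly increasing")
  if (!is.finite(concentration_M) || concentration_M <= 0)
    stop("concentration must be positive")
  structure(list(times_s = times_s, intensities = intensities,
                 concentration_M = concentration_M),
            class = "binding_timelapse")
}

#' Saturation binding model
#'
#' `I(t) = Imax * (1 - exp(-kobs * (t - t0))) + b`, clamped so that
#' `I(t < t0) = b`: the delay `t0` absorbs the arbitrary moment at which dye
#' was added, before which only background is recorded.
#'
#' @param t times (s).
#' @param Imax amplitude (a.u.); @param kobs observed rate (1/s);
#' @param t0 delay (s); @param b background (a.u.).
#' @return model intensities.
#' @export
binding_model <- function(t, Imax, kobs, t0, b) {
  b + Imax * (1 - exp(-kobs * pmax(t - t0, 0)))
}

# Deterministic initialization: background from the floor, amplitude from the
# range, rate from the log-linearized tail, onset from the 5% crossing.
kinetics_start <- function(t, I) {
  b0 <- min(I)
  Imax0 <- max(I) - min(I)
  plateau <- b0 + Imax0
  y <- plateau - I
  keep <- y > 1e-3 * Imax0
  kobs0 <- NA_real_
  if (sum(keep) >= 3) {
    sl <- stats::coef(stats::lm(log(y[keep]) ~ t[keep]))[2]
    if (is.finite(sl) && sl < 0) kobs0 <- -sl
  }
  if (!is.finite(kobs0)) kobs0 <- 3 / diff(range(t))
  above <- which(I > b0 + 0.05 * Imax0)
  t00 <- if (length(above)) t[above[1]] else t[1]
  list(Imax = Imax0, kobs = kobs0, t0 = t00, b = b0)
}

#' Fit a binding timelapse to the saturation model
#'
#' Nonlinear least squares (Levenberg-Marquardt) for `(Imax, kobs, t0, b)`
#' with a deterministic multistart over rate guesses `{0.3, 1, 3} x kobs0`,
#' where the starting values come from [kinetics_start] heuristics. Bounds:
#' `kobs` in `(1e-7, 1)` 1/s, `Imax > 0`, `t0` in `[0, t_max/2]` — physically
#' plausible for hour-scale binding.
#'
#' @param tl a [binding_timelapse()].
#' @return An object of class `kinetics_fit`: list with `Imax`, `kobs`, `t0`,
#'   `b`, standard errors `se` (named vector), `rms` residual root mean
#'   square, `concentration_M`, and the `fit` object.
#' @export
fit_binding_timelapse <- function(tl) {
  stopifnot(inherits(tl, "binding_timelapse"))
  t <- tl$times_s; I <- tl$intensities
  if (diff(range(I)) < 1e-9 * abs(mean(I)))
    stop("trace is flat: kinetics not identifiable")
  s0 <- kinetics_start(t, I)
  lower <- c(Imax = 1e-12, kobs = 1e-7, t0 = 0, b = -Inf)
  upper <- c(Imax = Inf, kobs = 1, t0 = max(t) / 2, b = Inf)
  best <- NULL
  for (mult in c(0.3, 1, 3)) {
    start <- list(Imax = s0$Imax, kobs = min(max(s0$kobs * mult, 2e-7), 0.99),
                  t0 = min(s0$t0, max(t) / 2), b = s0$b)
    fit <- tryCatch(
      minpack.lm::nlsLM(I ~ binding_model(t, Imax, kobs, t0, b),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(stats::residuals(fit)^2))
    if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
  }
  if (is.null(best))
    stop("kinetics fit failed to converge from all starting points")
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4), names(cf)))
  structure(list(Imax = unname(cf["Imax"]), kobs = unname(cf["kobs"]),
                 t0 = unname(cf["t0"]), b = unname(cf["b"]),
                 se = se, rms = best$rms, df = length(t) - 4L,
                 concentration_M = tl$concentration_M, fit = fit),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetics_fit: kobs=%.4g 1/s, Imax=%.4g, t0=%.4g s, b=%.4g, rms=%.3g>\n",
    x$kobs, x$Imax, x$t0, x$b, x$rms))
  invisible(x)
}

#' 95% confidence interval for the fitted kobs
#'
#' t-based interval from the nonlinear fit's standard error.
#'
#' @param fit a `kinetics_fit`.
#' @param level confidence level.
#' @return numeric length-2, `c(lower, upper)`.
#' @export
kobs_confint <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "kinetics_fit"))
  q <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  fit$kobs + c(-1, 1) * q * unname(fit$se["kobs"])
}

#' Regress observed rates against concentration
#'
#' Under pseudo-first-order conditions `kobs = kon * C + koff`, so the slope
#' of `kobs` versus dye concentration is the association rate `kon` and the
#' intercept the dissociation rate `koff`; `KD = koff / kon`. The regression
#' is ordinary least squares, or inverse-variance weighted when `weights` are
#' supplied. 95% CIs use the t distribution on the regression standard errors.
#'
#' @param concentration_M dye concentrations (molar), at least 2 distinct.
#' @param kobs observed rates (1/s), same length.
#' @param weights optional positive weights (e.g. `1/se^2`).
#' @return An object of class `rate_constants`: `kon`, `koff`, `KD`
#'   (`= koff/kon`, `NA` with a warning when the intercept is nonpositive),
#'   `se` (named: kon, koff), `ci` (2x2 matrix), and the `lm` fit.
#' @export
fit_rate_line <- function(concentration_M, kobs, weights = NULL) {
  stopifnot(length(concentration_M) == length(kobs))
  if (length(unique(concentration_M)) < 2L)
    stop("need at least 2 distinct concentrations")
  df <- data.frame(C = concentration_M, kobs = kobs)
  fit <- if (is.null(weights)) stats::lm(kobs ~ C, data = df)
         else stats::lm(kobs ~ C, data = df, weights = weights)
  cf <- stats::coef(fit)
  kon <- unname(cf["C"]); koff <- unname(cf["(Intercept)"])
  # exact (noiseless) points trip summary.lm's perfect-fit warning; the
  # zero SEs it returns are correct there
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- c(kon = sm["C", "Std. Error"], koff = sm["(Intercept)", "Std. Error"])
  ci <- if (stats::df.residual(fit) >= 1)
    tryCatch(suppressWarnings(stats::confint(fit, level = 0.95)),
             error = function(e) NULL)
  kd <- if (koff > 0 && kon > 0) koff / kon else NA_real_
  if (is.na(kd))
    warning("nonpositive fitted intercept or slope: KD not available")
  structure(list(kon = kon, koff = koff, KD = kd, se = se, ci = ci, fit = fit),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("<rate_constants: kon=%.4g 1/(M s), koff=%.4g 1/s, KD=%.4g M>\n",
              x$kon, x$koff, x$KD))
  invisible(x)
}

#' Dissociation constant from rate constants
#'
#' `KD = koff / kon`: the dye concentration at which half of the binding
#' sites are occupied at equilibrium.
#'
#' @param kon association rate (M^-1 s^-1), `> 0`.
#' @param koff dissociation rate (s^-1), `>= 0`.
#' @return KD in molar.
#' @export
dissociation_constant <- function(kon, koff) {
  if (any(kon <= 0)) stop("kon must be positive")
  if (any(koff < 0)) stop("koff must be nonnegative")
  koff / kon
}

#' Predicted observed rate at a concentration
#'
#' @param rc a `rate_constants` object (or any list with `kon`, `koff`).
#' @param concentration_M dye concentration (molar), `>= 0`.
#' @return `kon * C + koff` (1/s).
#' @export
predict_kobs <- function(rc, concentration_M) {
  if (any(concentration_M < 0)) stop("concentration must be nonnegative")
  rc$kon * concentration_M + rc$koff
}

#' Delay-free time to reach a fraction of the plateau
#'
#' For the saturation model the time at which the signal reaches fraction
#' `f` of `Imax` (ignoring the onset delay) is `-log(1 - f) / kobs`.
#'
#' @inheritParams predict_kobs
#' @param f target fraction in `[0, 1)`.
#' @return time in seconds.
#' @export
time_to_fraction <- function(rc, concentration_M, f) {
  if (any(f < 0 | f >= 1)) stop("fraction must lie in [0, 1)")
  -log(1 - f) / predict_kobs(rc, concentration_M)
}

#' Two-stage kinetics pipeline
#'
#' Fits every timelapse, regresses the fitted `kobs` against concentration,
#' and returns both stages.
#'
#' @param timelapses list of [binding_timelapse()] objects.
#' @param weighted if `TRUE`, weight the rate line by `1/se(kobs)^2`.
#' @return list with `fits` (list of `kinetics_fit`) and `rates`
#'   (`rate_constants`).
#' @export
kinetics_pipeline <- function(timelapses, weighted = FALSE) {
  fits <- lapply(timelapses, fit_binding_timelapse)
  conc <- vapply(fits, `[[`, numeric(1), "concentration_M")
  kobs <- vapply(fits, `[[`, numeric(1), "kobs")
  w <- if (weighted) {
    se <- vapply(fits, function(f) unname(f$se["kobs"]), numeric(1))
    1 / se^2
  }
  rates <- fit_rate_line(conc, kobs, weights = w)
  list(fits = fits, rates = rates)
}
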