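#' Photophysical parameters of one dye state
#'
#' Bundles the peak molar extinction, quantum yield, absorbance spectrum
#' (stored for a reference condition: 5 uM dye, 1 cm path; Beer-Lambert
#' scaling to other concentrations is linear) and emission spectrum of a
#' fluorophore in one binding state.
#'
#' @param epsilon_peak molar extinction at peak absorbance (M^-1 cm^-1), `> 0`.
#' @param phi fluorescence quantum yield in `[0, 1]`.
#' @param absorbance a [spectrum()] of kind `"absorbance"`.
#' @param emission a [spectrum()] of kind `"emission"` (arbitrary units).
#' @return An object of class `dye_state`.
#' @export
dye_state <- function(epsilon_peak, phi, absorbance, emission) {
  stopifnot(inherits(absorbance, "spectrum"), inherits(emission, "spectrum"))
  if (absorbance$kind != "absorbance") stop("absorbance spectrum has wrong kind")
  if (emission$kind != "emission") stop("emission spectrum has wrong kind")
  if (!is.finite(epsilon_peak) || epsilon_peak <= 0)
    stop("epsilon_peak must be positive")
  if (!is.finite(phi) || phi < 0 || phi > 1)
    stop("phi must lie in [0, 1]")
  structure(list(epsilon_peak = epsilon_peak, phi = phi,
                 absorbance = absorbance, emission = emission),
            class = "dye_state")
}

#' Two-state model of a fluorogenic dye
#'
#' The unbound and glycan-bound states of a turn-on dye. The two states must
#' be defined on overlapping wavelength ranges so that mixtures can be
#' evaluated at shared acquisition settings.
#'
#' @param unbound,bound [dye_state()] objects.
#' @return An object of class `two_state_dye`.
#' @export
two_state_dye <- function(unbound, bound) {
  stopifnot(inherits(unbound, "dye_state"), inherits(bound, "dye_state"))
  for (slot in c("absorbance", "emission")) {
    r1 <- range(unbound[[slot]]$wavelengths_nm)
    r2 <- range(bound[[slot]]$wavelengths_nm)
    if (max(r1[1], r2[1]) >= min(r1[2], r2[2]))
      stop(sprintf("%s spectra of the two states do not overlap", slot))
  }
  structure(list(unbound = unbound, bound = bound), class = "two_state_dye")
}

#' Acquisition settings: excitation line and emission band
#'
#' @param excitation_nm single excitation wavelength (nm).
#' @param emission_band `c(low_nm, high_nm)`; `high_nm = Inf` means longpass.
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(excitation_nm, emission_band) {
  stopifnot(length(excitation_nm) == 1L, length(emission_band) == 2L)
  if (!(emission_band[1] < emission_band[2]))
    stop("emission band must satisfy low < high")
  structure(list(excitation_nm = as.numeric(excitation_nm),
                 emission_band = as.numeric(emission_band)),
            class = "acquisition_settings")
}

#' Wavelength-specific excitation coefficient
#'
#' The fraction of incident photons converted to emitted photons at a given
#' excitation wavelength, `Phi * (1 - 10^(-A))`, where `A` is the absorbance
#' at that wavelength. The proportionality constant is taken as 1; every
#' downstream quantity is a ratio in which it cancels.
#'
#' @param phi quantum yield in `[0, 1]`.
#' @param absorbance_at_ex optical density at the excitation wavelength, `>= 0`.
#' @return dimensionless coefficient in `[0, phi]`.
#' @export
excitation_coefficient <- function(phi, absorbance_at_ex) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  if (any(absorbance_at_ex < 0)) stop("absorbance must be nonnegative")
  phi * (1 - 10^(-absorbance_at_ex))
}

#' Renormalize an emission spectrum to an excitation setting
#'
#' Scales an emission spectrum by the excitation coefficient at the chosen
#' excitation wavelength, making spectra measured under different excitation
#' conditions comparable.
#'
#' @param emission a [spectrum()] of kind `"emission"`.
#' @inheritParams excitation_coefficient
#' @return a [spectrum()] with scaled values, same wavelengths.
#' @export
renormalize_emission <- function(emission, phi, absorbance_at_ex) {
  stopifnot(inherits(emission, "spectrum"))
  if (emission$kind != "emission")
    stop("renormalize_emission expects an emission spectrum")
  coef <- excitation_coefficient(phi, absorbance_at_ex)
  spectrum(emission$wavelengths_nm, emission$values * coef, kind = "emission")
}

state_signal <- function(state, settings) {
  a_ex <- interp_spectrum(state$absorbance, settings$excitation_nm)
  excitation_coefficient(state$phi, a_ex) *
    integrate_band(state$emission, settings$emission_band)
}

#' Detected signal of a bound/unbound dye mixture
#'
#' Linear two-population mixing: each state contributes its excitation
#' coefficient at the excitation line times the trapezoidal integral of its
#' emission spectrum over the detection band, weighted by the fraction bound.
#'
#' @param model a [two_state_dye()].
#' @param fraction_bound fraction of dye in the bound state, in `[0, 1]`.
#' @param settings an [acquisition_settings()].
#' @return intensity (arbitrary units).
#' @export
signal_at_settings <- function(model, fraction_bound, settings) {
  stopifnot(inherits(model, "two_state_dye"),
            inherits(settings, "acquisition_settings"))
  if (any(fraction_bound < 0 | fraction_bound > 1))
    stop("fraction_bound must lie in [0, 1]")
  sb <- state_signal(model$bound, settings)
  su <- state_signal(model$unbound, settings)
  fraction_bound * sb + (1 - fraction_bound) * su
}

#' Fluorogenic contrast (delta F / F)
#'
#' Relative signal change between bound and unbound states at fixed
#' acquisition settings: `(bound - unbound) / unbound`.
#'
#' @param bound_signal,unbound_signal intensities; `unbound_signal > 0`.
#' @return dimensionless contrast (`7.3` means an 8.3-fold turn-on).
#' @export
contrast_dff <- function(bound_signal, unbound_signal) {
  if (any(unbound_signal <= 0)) stop("unbound signal must be positive")
  (bound_signal - unbound_signal) / unbound_signal
}

#' Contrast of a dye model at given acquisition settings
#'
#' Convenience wrapper: `contrast_dff` of the fully bound versus fully
#' unbound signal of `model` under `settings`.
#'
#' @inheritParams signal_at_settings
#' @return dimensionless contrast.
#' @export
model_contrast <- function(model, settings) {
  contrast_dff(signal_at_settings(model, 1, settings),
               signal_at_settings(model, 0, settings))
}
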