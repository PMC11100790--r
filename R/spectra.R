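#' Construct a spectrum
#'
#' A spectrum is a sampled curve over wavelength: absorbance (unitless optical
#' density), an excitation response, or an emission intensity (arbitrary
#' units). Wavelengths must be strictly increasing and values nonnegative.
#'
#' @param wavelengths_nm numeric, strictly increasing wavelengths in nm.
#' @param values numeric, same length as `wavelengths_nm`, all `>= 0`.
#' @param kind one of `"absorbance"`, `"excitation"`, `"emission"`.
#' @return An object of class `spectrum`: a list with elements
#'   `wavelengths_nm`, `values`, `kind`.
#' @export
spectrum <- function(wavelengths_nm, values,
                     kind = c("absorbance", "excitation", "emission")) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have the same length")
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least two samples")
  if (any(!is.finite(wavelengths_nm)) || any(!is.finite(values)))
    stop("spectrum contains non-finite entries")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(values < 0))
    stop("spectrum values must be nonnegative")
  structure(list(wavelengths_nm = wavelengths_nm, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d samples, %.1f-%.1f nm>\n", x$kind,
              length(x$values), min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Interpolate a spectrum at arbitrary wavelengths
#'
#' Linear interpolation between grid points. Queries outside the stored range
#' are an error: extrapolating a measured spectrum invents photophysics.
#'
#' @param s a [spectrum()].
#' @param wavelength_nm numeric vector of query wavelengths.
#' @return numeric vector of interpolated values.
#' @export
interp_spectrum <- function(s, wavelength_nm) {
  stopifnot(inherits(s, "spectrum"))
  rng <- range(s$wavelengths_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop(sprintf("wavelength outside stored range [%.1f, %.1f] nm",
                 rng[1], rng[2]))
  stats::approx(s$wavelengths_nm, s$values, xout = wavelength_nm,
                method = "linear", ties = "ordered")$y
}

#' Integrate a spectrum over an emission band
#'
#' Trapezoidal rule on the stored grid, clipped to the band. The band edges
#' are included by linear interpolation when they fall between grid points.
#' An unbounded upper edge (`Inf`, i.e. a longpass filter) integrates to the
#' last stored wavelength.
#'
#' @param s a [spectrum()].
#' @param band numeric length-2, `c(low_nm, high_nm)`; `high_nm` may be `Inf`.
#' @return the integral (value units times nm).
#' @export
integrate_band <- function(s, band) {
  stopifnot(inherits(s, "spectrum"), length(band) == 2L)
  lo <- band[1]; hi <- band[2]
  if (!(lo < hi)) stop("band must satisfy low < high")
  wl <- s$wavelengths_nm
  lo <- max(lo, wl[1])
  hi <- min(hi, wl[length(wl)])
  if (hi <= lo) return(0)
  inside <- wl > lo & wl < hi
  xs <- c(lo, wl[inside], hi)
  ys <- c(interp_spectrum(s, lo), s$values[inside], interp_spectrum(s, hi))
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Read / write a spectrum as two-column CSV
#'
#' The on-disk format is `wavelength_nm,value` with a one-line header.
#'
#' @param path file path.
#' @param kind spectrum kind for the object constructed on read.
#' @return `read_spectrum_csv` returns a [spectrum()]; `write_spectrum_csv`
#'   returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, kind = "absorbance") {
  df <- read_table(path, required = c("wavelength_nm", "value"))
  spectrum(df$wavelength_nm, df$value, kind = kind)
}

#' @rdname read_spectrum_csv
#' @param s a [spectrum()] to write.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  write_table(data.frame(wavelength_nm = s$wavelengths_nm, value = s$values),
              path)
}
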