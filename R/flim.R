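#' A photon-arrival decay histogram
#'
#' Photon counts in uniform time bins spanning one laser period
#' (`1 / rep_rate_hz`).
#'
#' @param counts nonnegative photon counts, one per bin.
#' @param rep_rate_hz laser repetition rate in Hz (default 8e7, an 80 MHz
#'   Ti:Sapphire source).
#' @return An object of class `decay_histogram` with `counts`,
#'   `bin_edges_ns` (uniform, length `nbins + 1`), and `rep_rate_hz`.
#' @export
decay_histogram <- function(counts, rep_rate_hz = 8e7) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (rep_rate_hz <= 0) stop("repetition rate must be positive")
  period_ns <- 1e9 / rep_rate_hz
  edges <- seq(0, period_ns, length.out = length(counts) + 1L)
  structure(list(counts = counts, bin_edges_ns = edges,
                 rep_rate_hz = rep_rate_hz),
            class = "decay_histogram")
}

#' Phasor coordinates of a mono-exponential lifetime
#'
#' Closed form: `g = 1 / (1 + (w*tau)^2)`, `s = w*tau / (1 + (w*tau)^2)`.
#' Mono-exponential decays lie on the universal semicircle `g^2 + s^2 = g`.
#'
#' @param tau_ns lifetime in ns, `>= 0`.
#' @param omega_rad_per_s angular modulation frequency (rad/s), typically
#'   `2 * pi * rep_rate`.
#' @return list with `g`, `s`.
#' @export
phasor_of_lifetime <- function(tau_ns, omega_rad_per_s) {
  if (any(tau_ns < 0)) stop("lifetime must be nonnegative")
  if (any(omega_rad_per_s <= 0)) stop("omega must be positive")
  wt <- omega_rad_per_s * tau_ns * 1e-9
  list(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Phasor transform of a decay histogram
#'
#' First-harmonic (or `harmonic`-th) discrete transform with bin midpoints:
#' `g = sum(c * cos(n w t)) / sum(c)`, `s = sum(c * sin(n w t)) / sum(c)`,
#' `w = 2 pi rep_rate`. No instrument-response deconvolution is applied.
#'
#' @param decay a [decay_histogram()] with positive total counts.
#' @param harmonic positive integer harmonic (default 1).
#' @return list with `g`, `s`.
#' @export
phasor_from_decay <- function(decay, harmonic = 1) {
  stopifnot(inherits(decay, "decay_histogram"))
  total <- sum(decay$counts)
  if (total <= 0) stop("decay has zero total counts")
  if (harmonic < 1 || harmonic != round(harmonic))
    stop("harmonic must be a positive integer")
  e <- decay$bin_edges_ns * 1e-9
  t_mid <- (utils::head(e, -1) + utils::tail(e, -1)) / 2
  w <- 2 * pi * decay$rep_rate_hz * harmonic
  list(g = sum(decay$counts * cos(w * t_mid)) / total,
       s = sum(decay$counts * sin(w * t_mid)) / total)
}

#' Per-pixel phasor image of a decay stack
#'
#' @param stack 3-D array ordered `(time bin, row, col)`.
#' @param rep_rate_hz laser repetition rate (Hz).
#' @param harmonic harmonic number.
#' @return An object of class `phasor_image`: list of matrices `g`, `s`, and
#'   `total` counts; pixels with zero counts get `NA` phasors.
#' @export
phasor_image <- function(stack, rep_rate_hz = 8e7, harmonic = 1) {
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be 3-D (bin, row, col)")
  period_ns <- 1e9 / rep_rate_hz
  edges <- seq(0, period_ns, length.out = d[1] + 1L)
  t_mid <- ((utils::head(edges, -1) + utils::tail(edges, -1)) / 2) * 1e-9
  w <- 2 * pi * rep_rate_hz * harmonic
  flat <- matrix(stack, nrow = d[1])        # bins x pixels
  total <- colSums(flat)
  g <- as.vector(crossprod(flat, cos(w * t_mid))) / total
  s <- as.vector(crossprod(flat, sin(w * t_mid))) / total
  g[total == 0] <- NA_real_; s[total == 0] <- NA_real_
  structure(list(g = matrix(g, d[2], d[3]), s = matrix(s, d[2], d[3]),
                 total = matrix(total, d[2], d[3])),
            class = "phasor_image")
}

#' Circular gate in phasor space
#'
#' @param g,s gate center coordinates.
#' @param radius gate radius, `> 0`.
#' @return An object of class `phasor_gate`.
#' @export
phasor_gate <- function(g, s, radius) {
  if (radius <= 0) stop("gate radius must be positive")
  structure(list(center = list(g = g, s = s), radius = radius),
            class = "phasor_gate")
}

#' Select pixels falling inside a phasor gate
#'
#' @param pimg a [phasor_image()].
#' @param gate a [phasor_gate()].
#' @return logical matrix; `NA` phasors (zero-count pixels) are `FALSE`.
#' @export
gate_pixels <- function(pimg, gate) {
  stopifnot(inherits(pimg, "phasor_image"), inherits(gate, "phasor_gate"))
  d2 <- (pimg$g - gate$center$g)^2 + (pimg$s - gate$center$s)^2
  mask <- d2 <= gate$radius^2
  mask[is.na(mask)] <- FALSE
  mask
}

#' Total-intensity image restricted to a gated population
#'
#' @param stack 3-D decay stack `(bin, row, col)`.
#' @param mask logical matrix matching the image plane.
#' @return matrix of per-pixel total counts where `mask` is `TRUE`, zero
#'   elsewhere.
#' @export
bandpass_intensity <- function(stack, mask) {
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be 3-D (bin, row, col)")
  if (!identical(dim(mask), d[2:3])) stop("mask shape does not match image plane")
  total <- matrix(colSums(matrix(stack, nrow = d[1])), d[2], d[3])
  total * (mask %in% TRUE)
}
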