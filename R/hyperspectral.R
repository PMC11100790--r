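#' An excitation-scan image cube
#'
#' A stack acquired by stepping the excitation wavelength at fixed emission
#' detection; each pixel carries an excitation spectrum.
#'
#' @param excitation_wavelengths_nm strictly increasing wavelengths, one per
#'   plane.
#' @param data 3-D array ordered `(wavelength, row, col)`, values `>= 0`.
#' @param emission_band detection band `c(low_nm, high_nm)`.
#' @return An object of class `hyperspectral_stack`.
#' @export
hyperspectral_stack <- function(excitation_wavelengths_nm, data,
                                emission_band = c(575, 630)) {
  wl <- as.numeric(excitation_wavelengths_nm)
  if (length(dim(data)) != 3L)
    stop("data must be a 3-D array (wavelength, row, col)")
  if (dim(data)[1] != length(wl))
    stop("first array dimension must match the wavelength grid")
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(data < 0)) stop("intensities must be nonnegative")
  structure(list(excitation_wavelengths_nm = wl, data = data,
                 emission_band = as.numeric(emission_band)),
            class = "hyperspectral_stack")
}

#' Mean excitation spectrum over a region of interest
#'
#' @param stack a [hyperspectral_stack()].
#' @param roi_mask logical matrix matching the image plane; must select at
#'   least one pixel.
#' @return a [spectrum()] of kind `"excitation"`.
#' @export
roi_mean_spectrum <- function(stack, roi_mask) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  d <- dim(stack$data)
  if (!identical(dim(roi_mask), d[2:3]))
    stop("ROI mask shape does not match the image plane")
  if (!any(roi_mask)) stop("ROI mask is empty")
  idx <- which(roi_mask)
  flat <- matrix(stack$data, nrow = d[1])   # wavelengths x pixels
  spectrum(stack$excitation_wavelengths_nm, rowMeans(flat[, idx, drop = FALSE]),
           kind = "excitation")
}

# Mean over non-overlapping b x b blocks; trailing partial blocks dropped.
block_mean <- function(m, b) {
  nr <- (nrow(m) %/% b) * b; nc <- (ncol(m) %/% b) * b
  if (nr < b || nc < b) stop("image smaller than one bin")
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  rs <- rowsum(m, rep(seq_len(nr %/% b), each = b))
  t(rowsum(t(rs), rep(seq_len(nc %/% b), each = b))) / (b * b)
}

#' Per-pixel peak-excitation-wavelength map
#'
#' Spatially bins the cube (block mean over `binning x binning` blocks,
#' trailing partial blocks dropped), then assigns each output pixel the grid
#' wavelength at which its excitation spectrum is maximal. Ties break toward
#' the lowest wavelength, so flat (noise-floor) pixels read maximally blue.
#' No sub-grid interpolation is performed: the map is grid-valued by design.
#'
#' @param stack a [hyperspectral_stack()].
#' @param binning positive integer block size (default 2).
#' @param intensity_floor pixels whose summed spectrum falls below
#'   `intensity_floor` times the global maximum summed spectrum are marked
#'   invalid (default 0: keep everything).
#' @return An object of class `spectral_peak_map`: list with `peak_nm`
#'   matrix and logical `valid_mask`.
#' @export
spectral_peak_map <- function(stack, binning = 2, intensity_floor = 0) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  if (binning < 1 || binning != round(binning)) stop("binning must be a positive integer")
  wl <- stack$excitation_wavelengths_nm
  nwl <- length(wl)
  planes <- lapply(seq_len(nwl), function(i) {
    p <- stack$data[i, , ]
    if (binning > 1) block_mean(p, binning) else p
  })
  cube <- array(unlist(planes), dim = c(dim(planes[[1]]), nwl))
  flat <- matrix(cube, ncol = nwl)            # pixels x wavelengths
  peak_idx <- max.col(flat, ties.method = "first")
  peak <- matrix(wl[peak_idx], nrow = dim(cube)[1])
  totals <- matrix(rowSums(flat), nrow = dim(cube)[1])
  valid <- totals >= intensity_floor * max(totals)
  structure(list(peak_nm = peak, valid_mask = valid),
            class = "spectral_peak_map")
}

#' Extract one excitation plane
#'
#' @param stack a [hyperspectral_stack()].
#' @param excitation_nm a wavelength that is exactly on the stored grid.
#' @return the corresponding image plane (matrix), unmodified.
#' @export
intensity_image <- function(stack, excitation_nm) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  i <- match(excitation_nm, stack$excitation_wavelengths_nm)
  if (is.na(i))
    stop(sprintf("wavelength %.1f nm not on the grid (%s nm)", excitation_nm,
                 paste(stack$excitation_wavelengths_nm, collapse = ", ")))
  stack$data[i, , ]
}
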