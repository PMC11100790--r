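#' A region-of-interest intensity trace
#'
#' @param times_s strictly increasing times (s), at least 10 samples.
#' @param intensities mean ROI intensities (a.u.).
#' @param roi identifier string.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(times_s, intensities, roi = "roi") {
  times_s <- as.numeric(times_s); intensities <- as.numeric(intensities)
  if (length(times_s) != length(intensities))
    stop("times and intensities must have the same length")
  if (length(times_s) < 10L) stop("need at least 10 samples")
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  structure(list(times_s = times_s, intensities = intensities, roi = roi),
            class = "roi_trace")
}

#' Extract ROI mean-intensity traces from a timelapse stack
#'
#' @param stack 3-D array ordered `(frame, row, col)`.
#' @param masks named list of logical matrices matching the image plane; each
#'   must select at least one pixel.
#' @param frame_interval_s time between frames (s).
#' @return list of [roi_trace()] objects, one per mask.
#' @export
roi_traces <- function(stack, masks, frame_interval_s = 60) {
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be 3-D (frame, row, col)")
  if (is.null(names(masks))) names(masks) <- paste0("roi", seq_along(masks))
  flat <- matrix(stack, nrow = d[1])   # frames x pixels
  times <- (seq_len(d[1]) - 1L) * frame_interval_s
  lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!identical(dim(m), d[2:3])) stop("mask shape does not match image plane")
    if (!any(m)) stop("empty ROI mask")
    roi_trace(times, rowMeans(flat[, which(m), drop = FALSE]), roi = nm)
  })
}

#' Photobleaching metrics for a trace
#'
#' `relative_change` compares the mean of the last `window_frac` of frames to
#' the mean of the first `window_frac` (windows hold at least 3 frames),
#' relative to the initial window. `normalized_slope` is the least-squares
#' slope of intensity versus time divided by the trace mean, reported per
#' hour. Both are invariant to multiplicative rescaling of the trace.
#'
#' @param trace a [roi_trace()].
#' @param window_frac fraction of frames in each end window (default 0.05).
#' @return list with `relative_change` and `normalized_slope` (1/h).
#' @export
bleaching_metric <- function(trace, window_frac = 0.05) {
  stopifnot(inherits(trace, "roi_trace"))
  n <- length(trace$intensities)
  w <- max(3L, floor(window_frac * n))
  first <- mean(trace$intensities[seq_len(w)])
  last <- mean(trace$intensities[seq.int(n - w + 1L, n)])
  if (first == 0) stop("initial window mean is zero")
  slope <- stats::coef(stats::lm(trace$intensities ~ trace$times_s))[2]
  list(relative_change = (last - first) / first,
       normalized_slope = unname(slope) / mean(trace$intensities) * 3600)
}
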