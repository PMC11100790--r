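#' Glycan-array layout
#'
#' Spot geometry of a printed glycan microarray: one center per spot, a disk
#' radius for signal, and an annulus (inner > spot radius) for the local
#' background estimate.
#'
#' @param centers data.frame with columns `glycan` (identifier; negative
#'   controls use `"control"`), `replicate`, `row`, `col` (pixel coordinates,
#'   1-based).
#' @param spot_radius disk radius in pixels.
#' @param annulus_radii `c(inner, outer)` annulus radii; `inner > spot_radius`.
#' @return An object of class `array_layout`.
#' @export
array_layout <- function(centers, spot_radius = 4, annulus_radii = c(6, 9)) {
  need <- c("glycan", "replicate", "row", "col")
  if (!all(need %in% names(centers)))
    stop("centers must have columns glycan, replicate, row, col")
  if (annulus_radii[1] <= spot_radius)
    stop("annulus inner radius must exceed the spot radius")
  if (annulus_radii[2] <= annulus_radii[1])
    stop("annulus outer radius must exceed the inner radius")
  structure(list(centers = centers, spot_radius = spot_radius,
                 annulus_radii = annulus_radii),
            class = "array_layout")
}

#' Default 100-glycan layout
#'
#' 100 glycans in 4 replicate spots plus two sets of 4 negative-control
#' spots (408 spots total) on a regular grid.
#'
#' @param pitch center-to-center spacing in pixels.
#' @param spot_radius,annulus_radii geometry passed to [array_layout()].
#' @param n_cols spots per grid row.
#' @return an [array_layout()].
#' @export
default_array_layout <- function(pitch = 20, spot_radius = 4,
                                 annulus_radii = c(6, 9), n_cols = 24) {
  glycans <- c(rep(sprintf("G%03d", 1:100), each = 4), rep("control", 8))
  reps <- c(rep(1:4, times = 100), 1:8)
  n <- length(glycans)
  n_rows <- ceiling(n / n_cols)
  idx <- seq_len(n) - 1L
  centers <- data.frame(
    glycan = glycans, replicate = reps,
    row = (idx %/% n_cols) * pitch + pitch,
    col = (idx %% n_cols) * pitch + pitch)
  layout <- array_layout(centers, spot_radius, annulus_radii)
  layout$image_dim <- c(n_rows * pitch + pitch, n_cols * pitch + pitch)
  layout
}

disk_values <- function(image, center, r_lo, r_hi) {
  rr <- floor(center[1] - r_hi):ceiling(center[1] + r_hi)
  cc <- floor(center[2] - r_hi):ceiling(center[2] + r_hi)
  if (min(rr) < 1 || min(cc) < 1 || max(rr) > nrow(image) || max(cc) > ncol(image))
    stop("spot geometry extends outside the image")
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  sel <- d2 > r_lo^2 & d2 <= r_hi^2
  image[rr, cc][sel]
}

#' Quantify one array spot
#'
#' Signal is the mean over the spot disk; the local background is the median
#' over the surrounding annulus (robust to bleed from neighboring spots);
#' `corrected = raw - background`; `background_sd` is the annulus SD.
#'
#' @param image numeric matrix.
#' @param center `c(row, col)` spot center (pixels, 1-based).
#' @param spot_radius disk radius (pixels).
#' @param annulus_radii `c(inner, outer)` annulus radii (pixels).
#' @return list with `raw`, `background`, `corrected`, `background_sd`.
#' @export
quantify_spot <- function(image, center, spot_radius, annulus_radii) {
  disk <- disk_values(image, center, -1, spot_radius)
  ann <- disk_values(image, center, annulus_radii[1], annulus_radii[2])
  raw <- mean(disk)
  bg <- stats::median(ann)
  list(raw = raw, background = bg, corrected = raw - bg,
       background_sd = stats::sd(ann))
}

#' Quantify every spot of an array
#'
#' @param image numeric matrix.
#' @param layout an [array_layout()].
#' @param normalize apply [normalize_within_array()] (set `FALSE` for e.g.
#'   blank arrays whose corrected values have no positive mean).
#' @return data.frame: one row per spot with layout columns plus `raw`,
#'   `background`, `corrected`, `background_sd`, and within-array
#'   `normalized` values (see [normalize_within_array()]).
#' @export
quantify_array <- function(image, layout, normalize = TRUE) {
  stopifnot(inherits(layout, "array_layout"))
  cen <- layout$centers
  q <- lapply(seq_len(nrow(cen)), function(i)
    quantify_spot(image, c(cen$row[i], cen$col[i]),
                  layout$spot_radius, layout$annulus_radii))
  out <- cbind(cen,
               raw = vapply(q, `[[`, numeric(1), "raw"),
               background = vapply(q, `[[`, numeric(1), "background"),
               corrected = vapply(q, `[[`, numeric(1), "corrected"),
               background_sd = vapply(q, `[[`, numeric(1), "background_sd"))
  if (normalize) out$normalized <- normalize_within_array(out$corrected)
  out
}

#' Within-array signal normalization
#'
#' Divides each background-corrected spot value by the array-wise mean of all
#' corrected spot values, removing array-to-array gain differences (imaging
#' condition drift). The result is dimensionless.
#'
#' @param corrected background-corrected spot values of one array.
#' @return normalized values; errors when the array mean is nonpositive.
#' @export
normalize_within_array <- function(corrected) {
  m <- mean(corrected)
  if (!is.finite(m) || m <= 0)
    stop("array-wise mean of corrected values is nonpositive: cannot normalize")
  corrected / m
}

#' Detection call against local background noise
#'
#' A glycan is called detected when its background-corrected signal strictly
#' exceeds twice the local-background standard deviation.
#'
#' @param corrected_mean mean corrected signal.
#' @param background_sd local background SD, `>= 0`.
#' @return logical.
#' @export
detection_call <- function(corrected_mean, background_sd) {
  if (any(background_sd < 0)) stop("background SD must be nonnegative")
  corrected_mean > 2 * background_sd
}

welch_stat <- function(m1, v1, n1, m0, v0, n0) {
  (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
}

welch_df <- function(v1, n1, v0, n0) {
  (v1 / n1 + v0 / n0)^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
}

#' Dunnett-corrected Welch comparisons against a shared control
#'
#' Computes a Welch (unequal-variance) t statistic for every glycan group
#' against the pooled negative-control values, then adjusts for the family of
#' comparisons with a Dunnett-type step: the adjusted p-value of group `i` is
#' the null probability that the maximum absolute Welch statistic across all
#' groups exceeds `|t_i|`. Because all comparisons share one control, the
#' statistics are correlated and no closed form exists under unequal
#' variances; the joint null is evaluated by seeded parametric Monte Carlo
#' with plug-in group standard deviations. Adjusted p-values are floored at
#' the raw Welch p-value, so adjustment can only increase p.
#'
#' @param groups list (or matrix with groups in columns) of replicate values
#'   per glycan; each group needs `n >= 2`.
#' @param control pooled negative-control values, `n >= 2`.
#' @param n_mc Monte Carlo draws for the joint null (default 1e5).
#' @param seed RNG seed for the Monte Carlo draw (local; the caller's RNG
#'   state is restored).
#' @return data.frame with `t` (Welch statistic), `df` (Satterthwaite),
#'   `p_raw` (two-sided Welch p), `p_adj` (Dunnett-adjusted).
#' @export
dunnett_vs_control <- function(groups, control, n_mc = 1e5, seed = 1234) {
  if (is.matrix(groups)) groups <- asplit(groups, 2)
  ns <- lengths(groups)
  if (any(ns < 2L) || length(control) < 2L)
    stop("each group and the control need at least 2 replicates")
  k <- length(groups)
  m0 <- mean(control); v0 <- stats::var(control); n0 <- length(control)
  ms <- vapply(groups, mean, numeric(1))
  vs <- vapply(groups, stats::var, numeric(1))
  t_obs <- welch_stat(ms, vs, ns, m0, v0, n0)
  dfs <- welch_df(vs, ns, v0, n0)
  p_raw <- 2 * stats::pt(-abs(t_obs), df = dfs)
  sds <- sqrt(vs)
  max_t <- with_seed(seed, {
    ctrl <- matrix(stats::rnorm(n_mc * n0, sd = sqrt(v0)), n_mc, n0)
    mc0 <- rowMeans(ctrl)
    vc0 <- (rowSums(ctrl^2) - n0 * mc0^2) / (n0 - 1)
    mx <- rep(0, n_mc)
    for (j in seq_len(k)) {
      g <- matrix(stats::rnorm(n_mc * ns[j], sd = sds[j]), n_mc, ns[j])
      mg <- rowMeans(g)
      vg <- (rowSums(g^2) - ns[j] * mg^2) / (ns[j] - 1)
      mx <- pmax(mx, abs(welch_stat(mg, vg, ns[j], mc0, vc0, n0)))
    }
    mx
  })
  p_adj <- vapply(abs(t_obs), function(ti) mean(max_t >= ti), numeric(1))
  p_adj <- pmin(1, pmax(p_adj, p_raw))
  data.frame(t = t_obs, df = dfs, p_raw = p_raw, p_adj = p_adj)
}

#' Full glycan-array analysis
#'
#' Quantifies all spots, normalizes within the array, calls detections
#' against local background noise, and tests every glycan against the pooled
#' negative controls with the Dunnett-corrected Welch procedure.
#'
#' @param image array image (matrix).
#' @param layout an [array_layout()].
#' @param alpha significance level for the `significant` flag.
#' @param n_mc,seed passed to [dunnett_vs_control()].
#' @return list with `spots` (per-spot table) and `glycans` (per-glycan
#'   table: `mean_normalized`, `detected`, `t`, `p_adj`, `significant`).
#' @export
analyze_array <- function(image, layout, alpha = 0.05, n_mc = 1e5, seed = 1234) {
  spots <- quantify_array(image, layout)
  is_ctrl <- spots$glycan == "control"
  if (!any(is_ctrl)) stop("layout has no control spots")
  glyc <- split(spots[!is_ctrl, ], spots$glycan[!is_ctrl])
  groups <- lapply(glyc, `[[`, "normalized")
  dn <- dunnett_vs_control(groups, spots$normalized[is_ctrl],
                           n_mc = n_mc, seed = seed)
  res <- data.frame(
    glycan = names(glyc),
    mean_normalized = vapply(glyc, function(g) mean(g$normalized), numeric(1)),
    detected = mapply(function(g) detection_call(mean(g$corrected),
                                                 mean(g$background_sd)),
                      glyc),
    t = dn$t, p_raw = dn$p_raw, p_adj = dn$p_adj,
    row.names = NULL)
  res$significant <- res$p_adj < alpha & res$t > 0
  list(spots = spots, glycans = res)
}
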