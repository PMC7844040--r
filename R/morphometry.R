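# Fibrillar morphometrics: fenestration (void) fraction, fiber diameter by
# FWHM profiling, centerline waviness, and layer thickness from boundaries.

#' Fenestration (void) fraction of a window
#'
#' Binarizes the window with Otsu's threshold and returns the fraction of
#' void (sub-threshold) pixels relative to the whole window, i.e.
#' void / (void + collagen). Invariant to linear intensity rescaling. A
#' constant window has no defined threshold: the fraction is computed
#' against a fixed fallback threshold and flagged.
#'
#' @param window numeric matrix.
#' @param fallback threshold used for constant windows; default half the
#'   window's maximum intensity.
#' @return One-row data.frame: `fraction`, `threshold`, `flag`.
#' @export
fenestration_fraction <- function(window, fallback = NULL) {
  rng <- range(window)
  if (rng[2] == rng[1]) {
    if (is.null(fallback)) fallback <- rng[2] / 2
    return(data.frame(fraction = mean(window <= fallback), threshold = fallback,
                      flag = TRUE))
  }
  scaled <- (window - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(scaled, range = c(0, 1), levels = 256)
  thr <- rng[1] + thr01 * (rng[2] - rng[1])
  data.frame(fraction = mean(window <= thr), threshold = thr, flag = FALSE)
}

# Unit normal of a polyline at each vertex (average of adjacent segment
# normals), in (row, col) pixel coordinates.
polyline_normals <- function(pts) {
  n <- nrow(pts)
  seg <- diff(pts)
  seg <- seg / sqrt(rowSums(seg^2))
  vert <- rbind(seg[1, , drop = FALSE],
                (seg[-nrow(seg), , drop = FALSE] + seg[-1, , drop = FALSE]) / 2,
                seg[nrow(seg), , drop = FALSE])
  vert <- vert / sqrt(rowSums(vert^2))
  cbind(-vert[, 2], vert[, 1])  # rotate tangent 90 degrees
}

#' Fiber diameter by perpendicular FWHM profiling
#'
#' Measures the full width at half maximum of the intensity profile
#' perpendicular to a fiber centerline at regularly spaced stations, and
#' returns the median (and spread) converted to micrometers. Stations whose
#' profile has no half-maximum crossing on both sides are skipped.
#'
#' @param image a `vf_image` or matrix with the fiber brighter than the
#'   background.
#' @param centerline two-column matrix of (row, col) pixel coordinates
#'   along the fiber.
#' @param pixel_pitch_um micrometers per pixel; taken from the image when a
#'   `vf_image` is supplied.
#' @param n_stations number of measurement stations; default 15.
#' @param halfwidth_px profile half-length perpendicular to the fiber, in
#'   pixels; default 15.
#' @return One-row data.frame: `diameter_um` (median), `sd_um`,
#'   `n_stations_used`.
#' @export
fiber_diameter <- function(image, centerline, pixel_pitch_um = NULL,
                           n_stations = 15, halfwidth_px = 15) {
  px <- as_pixels(image)
  if (is.null(pixel_pitch_um))
    pixel_pitch_um <- if (inherits(image, "vf_image")) image$pixel_pitch_x_um else 1
  stations <- unique(round(seq(1, nrow(centerline), length.out = n_stations)))
  normals <- polyline_normals(centerline)
  widths <- c()
  ss <- seq(-halfwidth_px, halfwidth_px, by = 0.25)
  for (k in stations) {
    rows <- centerline[k, 1] + ss * normals[k, 1]
    cols <- centerline[k, 2] + ss * normals[k, 2]
    inb <- rows >= 1 & rows <= nrow(px) & cols >= 1 & cols <= ncol(px)
    if (sum(inb) < 5) next
    prof <- bilinear_sample(px, rows[inb], cols[inb])
    s <- ss[inb]
    pk <- which.max(prof)
    half <- (max(prof) + min(prof)) / 2
    lo <- which(prof[seq_len(pk)] < half)
    hi <- which(prof[pk:length(prof)] < half)
    if (length(lo) == 0 || length(hi) == 0) next
    il <- max(lo); ih <- pk + min(hi) - 1
    # linear interpolation of the two half-maximum crossings
    sl <- s[il] + (half - prof[il]) / (prof[il + 1] - prof[il]) * (s[il + 1] - s[il])
    sh <- s[ih - 1] + (half - prof[ih - 1]) / (prof[ih] - prof[ih - 1]) *
      (s[ih] - s[ih - 1])
    widths <- c(widths, sh - sl)
  }
  if (length(widths) == 0) stop("no station produced a half-maximum crossing")
  data.frame(diameter_um = stats::median(widths) * pixel_pitch_um,
             sd_um = if (length(widths) > 1) stats::sd(widths) * pixel_pitch_um else 0,
             n_stations_used = length(widths))
}

#' Waviness (period and amplitude) of a fiber centerline
#'
#' Characterizes the quasi-sinusoidal undulation of a centerline: the
#' points are projected onto their principal axis, the transverse
#' displacement is detrended (linear), and local extrema with magnitude of
#' at least 20% of the displacement SD are detected. The spatial period is
#' the mean peak-to-peak spacing along the axis and the amplitude the mean
#' absolute displacement at the extrema. At the `"global"` scale a moving-
#' average low-pass with cut-off 3x the local period is applied first, so
#' bundle-scale undulation is measured instead of fiber-scale wiggles.
#'
#' @param centerline two-column matrix of (row, col) pixel coordinates.
#' @param scale `"local"` (fiber scale, default) or `"global"` (bundle
#'   scale).
#' @param pixel_pitch_um micrometers per pixel.
#' @return One-row data.frame: `period_um`, `amplitude_um`, `n_peaks`,
#'   `flag` (TRUE when fewer than 2 peaks exist and the result is
#'   undefined).
#' @export
waviness <- function(centerline, scale = c("local", "global"),
                     pixel_pitch_um = 1) {
  scale <- match.arg(scale)
  ctr <- scale(centerline, scale = FALSE)
  ev <- eigen(stats::cov(ctr), symmetric = TRUE)
  u <- ctr %*% ev$vectors[, 1]
  d <- ctr %*% ev$vectors[, 2]
  o <- order(u)
  u <- u[o]; d <- d[o]
  # uniform resampling along the axis, then linear detrend
  ug <- seq(u[1], u[length(u)], length.out = length(u))
  dg <- stats::approx(u, d, xout = ug, ties = mean)$y
  dg <- stats::lm.fit(cbind(1, ug), dg)$residuals
  res <- waviness_extrema(ug, dg)
  if (scale == "global") {
    if (is.na(res$period)) return(undefined_waviness())
    cutoff <- 3 * res$period
    wlen <- max(3, round(cutoff / mean(diff(ug))))
    if (wlen %% 2 == 0) wlen <- wlen + 1
    if (wlen >= length(dg)) return(undefined_waviness())
    kern <- rep(1 / wlen, wlen)
    sm <- stats::filter(dg, kern, sides = 2)
    keep <- !is.na(sm)
    res <- waviness_extrema(ug[keep], as.numeric(sm[keep]))
  }
  if (is.na(res$period)) return(undefined_waviness())
  data.frame(period_um = res$period * pixel_pitch_um,
             amplitude_um = res$amplitude * pixel_pitch_um,
             n_peaks = res$n_peaks, flag = FALSE)
}

undefined_waviness <- function() {
  data.frame(period_um = NA_real_, amplitude_um = NA_real_, n_peaks = 0L,
             flag = TRUE)
}

waviness_extrema <- function(u, d) {
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0)
    return(list(period = NA_real_, amplitude = NA_real_, n_peaks = 0L))
  dd <- diff(d)
  ext <- which(dd[-length(dd)] * dd[-1] < 0) + 1
  ext <- ext[abs(d[ext]) >= 0.2 * sdd]
  peaks <- ext[d[ext] > 0]
  if (length(peaks) < 2)
    return(list(period = NA_real_, amplitude = NA_real_, n_peaks = length(peaks)))
  list(period = mean(diff(u[peaks])), amplitude = mean(abs(d[ext])),
       n_peaks = length(peaks))
}

#' Layer thicknesses from ordered boundary positions
#'
#' Successive differences of boundary depth positions times the pixel
#' pitch. For OCT-derived boundaries measured along an inclined optical
#' path, apply [path_to_depth()] first (or pass `angle_deg`/`refr_index`).
#'
#' @param boundaries strictly increasing numeric vector of boundary
#'   positions, pixels.
#' @param pixel_pitch_um micrometers per pixel.
#' @param angle_deg,refr_index optional path-to-depth correction applied to
#'   the differences; defaults 0 and 1 (no correction).
#' @return Numeric vector of per-layer thicknesses, micrometers.
#' @export
layer_thickness <- function(boundaries, pixel_pitch_um = 1, angle_deg = 0,
                            refr_index = 1) {
  if (length(boundaries) < 2) stop("need at least two boundaries")
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  path_to_depth(diff(boundaries) * pixel_pitch_um, angle_deg, refr_index)
}
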