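# OCT branch: frame averaging, normalization, surface detection, 45-degree
# midline extraction, single-scattering log-linear attenuation fitting and
# changepoint layer segmentation.
#
# Under the single-scattering (Beer-Lambert) model the averaged OCT signal
# decays as I(z) ~ I0 * exp(-2 * mu_t * z) with z the physical depth; the
# factor 2 accounts for round-trip attenuation. Fitted coefficients are
# *relative*: no confocal or roll-off calibration is applied, and negative
# fitted values are flagged rather than clamped.

#' Average consecutive B-scan frames
#'
#' Pixelwise arithmetic mean of `k` consecutive frames, the standard
#' speckle-reduction step applied before texture and attenuation analysis.
#'
#' @param frames a `vf_stack` (list of `vf_image`s) or list of matrices.
#' @param k number of consecutive frames to average; default 5.
#' @param start index of the first frame; default 1.
#' @return A `vf_image` (metadata from the first frame), or a plain matrix
#'   if the input was a list of matrices.
#' @export
average_frames <- function(frames, k = 5, start = 1) {
  if (length(frames) < start + k - 1) stop("fewer than k frames available")
  sel <- frames[start:(start + k - 1)]
  mats <- lapply(sel, as_pixels)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("frame shapes differ")
  avg <- Reduce(`+`, mats) / k
  if (inherits(sel[[1]], "vf_image")) {
    out <- sel[[1]]
    out$pixels <- avg
    out
  } else avg
}

#' Normalize a B-scan to [0, 1]
#'
#' Divides by the 99.9th-percentile intensity (robust to isolated hot
#' pixels) and clips to [0, 1], removing acquisition-to-acquisition scale
#' variation. The normalization constant is recorded as attribute
#' `norm_constant`.
#'
#' @param bscan a `vf_image` or matrix with a positive maximum.
#' @param probs percentile used as the normalization constant; default 0.999.
#' @return Matrix in [0, 1] with attribute `norm_constant`.
#' @export
normalize_bscan <- function(bscan, probs = 0.999) {
  px <- as_pixels(bscan)
  if (max(px) <= 0) stop("all-zero B-scan cannot be normalized")
  qn <- stats::quantile(px, probs, names = FALSE)
  if (qn <= 0) qn <- max(px)
  out <- pmin(px / qn, 1)
  attr(out, "norm_constant") <- qn
  out
}

#' Detect the tissue surface in a B-scan
#'
#' Anchors z = 0 at the epithelium surface: for each column, the first
#' sample exceeding an adaptive threshold (median of the air region plus 6
#' median absolute deviations) is taken as the surface, then the surface
#' line is median-filtered across columns. The air region is estimated from
#' the rows above the first coarse intensity rise of the row-mean profile.
#' Columns with no crossing are flagged and interpolated from neighbors; if
#' no air region or no surface can be found, all columns are flagged.
#'
#' @param bscan normalized B-scan matrix (see [normalize_bscan()]).
#' @param smooth_px width of the across-column median filter (odd);
#'   default 5.
#' @return A list: integer vector `surface` (row index per column; NA if
#'   undetectable everywhere) and logical vector `flagged`.
#' @export
detect_surface <- function(bscan, smooth_px = 5) {
  px <- as_pixels(bscan)
  nr <- nrow(px); nc <- ncol(px)
  prof <- rowMeans(px)
  coarse <- min(prof) + 0.2 * diff(range(prof))
  rc <- which(prof > coarse)[1]
  if (is.na(rc) || rc < 4)
    return(list(surface = rep(NA_integer_, nc), flagged = rep(TRUE, nc)))
  air <- px[seq_len(rc - 3), , drop = FALSE]
  thr <- stats::median(air) + 6 * stats::mad(air)
  surf <- rep(NA_integer_, nc)
  for (j in seq_len(nc)) {
    hit <- which(px[, j] > thr)[1]
    if (!is.na(hit)) surf[j] <- hit
  }
  flagged <- is.na(surf)
  if (all(flagged))
    return(list(surface = surf, flagged = flagged))
  if (any(flagged)) {
    ok <- which(!flagged)
    surf[flagged] <- round(stats::approx(ok, surf[ok], xout = which(flagged),
                                         rule = 2)$y)
  }
  if (smooth_px > 1 && nc >= smooth_px)
    surf <- as.integer(stats::runmed(surf, smooth_px, endrule = "median"))
  list(surface = as.integer(surf), flagged = flagged)
}

#' Extract a depth profile (A-line) along an inclined midline
#'
#' Samples the B-scan by bilinear interpolation along a straight line
#' starting at the detected surface of the edge column, inclined
#' `angle_deg` from the surface normal (the 45-degree midline protocol by
#' default). Sample spacing is one axial pixel of optical path per step
#' along the line (isotropic pixel geometry is assumed for inclined lines).
#'
#' @param bscan normalized B-scan matrix.
#' @param surface result of [detect_surface()] or an integer vector of
#'   per-column surface rows.
#' @param edge_col column at which the line starts; default the lateral
#'   midpoint of the image (the anatomical edge cannot be inferred from
#'   pixels alone).
#' @param angle_deg inclination from the surface normal; default 45.
#' @param direction +1 to advance toward larger columns, -1 toward smaller.
#' @param pixel_pitch_z_um optical axial pitch per pixel step, um.
#' @param n_avg number of parallel lines (laterally offset by one pixel
#'   each, centered on `edge_col`) whose profiles are averaged to suppress
#'   residual speckle; default 1 (single line).
#' @return An object of class `vf_aline`: `intensity`, `step_um_optical`
#'   (optical path per sample), `path_angle_deg`, `surface_index` (1),
#'   `truncated` (TRUE if the line left the image laterally).
#' @export
extract_midline <- function(bscan, surface, edge_col = NULL, angle_deg = 45,
                            direction = 1, pixel_pitch_z_um = 1, n_avg = 1) {
  px <- as_pixels(bscan)
  nr <- nrow(px); nc <- ncol(px)
  surf <- if (is.list(surface)) surface$surface else surface
  if (is.null(edge_col)) edge_col <- round(nc / 2)
  r0 <- surf[edge_col]
  if (is.na(r0)) stop("surface undetected at the edge column")
  offsets <- seq_len(n_avg) - (n_avg + 1) / 2
  offsets <- offsets[edge_col + offsets >= 1 & edge_col + offsets <= nc]
  a <- angle_deg * pi / 180
  dr <- cos(a); dc <- direction * sin(a)
  tmax <- (nr - r0) / max(dr, 1e-12)
  if (dc > 0) tmax_c <- (nc - max(edge_col + offsets)) / dc
  else if (dc < 0) tmax_c <- (min(edge_col + offsets) - 1) / (-dc)
  else tmax_c <- Inf
  truncated <- tmax_c < tmax
  tend <- floor(min(tmax, tmax_c))
  ts <- 0:max(tend, 0)
  rows <- r0 + ts * dr
  intensity <- rowMeans(vapply(offsets, function(o)
    bilinear_sample(px, rows, edge_col + o + ts * dc),
    numeric(length(ts))))
  structure(list(intensity = intensity,
                 step_um_optical = pixel_pitch_z_um,
                 path_angle_deg = angle_deg, surface_index = 1L,
                 truncated = truncated),
            class = "vf_aline")
}

bilinear_sample <- function(px, rows, cols) {
  nr <- nrow(px); nc <- ncol(px)
  r0 <- pmin(pmax(floor(rows), 1), nr - 1)
  c0 <- pmin(pmax(floor(cols), 1), nc - 1)
  fr <- rows - r0; fc <- cols - c0
  px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    px[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    px[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    px[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Convert optical path length to physical depth
#'
#' Projects an optical path measured along a line inclined `angle_deg` from
#' the surface normal onto the depth axis (Pythagorean correction) and
#' converts from optical to physical length through the tissue refractive
#' index: `depth = path * cos(angle) / n`.
#'
#' @param path_um_optical optical path length, micrometers (>= 0).
#' @param angle_deg inclination from the surface normal; |angle| < 90.
#' @param refr_index tissue group refractive index; default 1.384.
#' @return Physical depth in micrometers.
#' @export
path_to_depth <- function(path_um_optical, angle_deg = 0, refr_index = 1.384) {
  if (any(path_um_optical < 0)) stop("path length must be >= 0")
  if (abs(angle_deg) >= 90) stop("|angle_deg| must be < 90")
  path_um_optical * cos(angle_deg * pi / 180) / refr_index
}

aline_depth_mm <- function(aline, refr_index = 1.384) {
  idx <- seq_along(aline$intensity)
  path_to_depth((idx - aline$surface_index) * aline$step_um_optical,
                aline$path_angle_deg, refr_index) / 1000
}

#' Fit a relative attenuation coefficient to an A-line
#'
#' Ordinary least squares of `ln(I)` on physical depth z (mm) over the fit
#' range; `mu_t = -slope / 2`, the factor 2 accounting for round-trip
#' attenuation. Nonpositive intensities in the range are dropped before
#' fitting. A negative fitted coefficient is allowed (the coefficient is
#' relative) but flagged.
#'
#' @param aline a `vf_aline` (see [extract_midline()]), or any list with
#'   `intensity`, `step_um_optical`, `path_angle_deg`, `surface_index`.
#' @param fit_range integer vector `c(start, end)` of sample indices;
#'   default the full profile from the surface.
#' @param refr_index tissue refractive index; default 1.384.
#' @param layer optional region label to record.
#' @return A list of class `vf_attenfit`: `mu_t_per_mm`, `slope`,
#'   `intercept_log`, `fit_range`, `r_squared`, `n_used`, `layer`,
#'   `negative_flag`.
#' @export
fit_attenuation <- function(aline, fit_range = NULL, refr_index = 1.384,
                            layer = NA_character_) {
  I <- aline$intensity
  if (is.null(fit_range)) fit_range <- c(aline$surface_index, length(I))
  idx <- fit_range[1]:fit_range[2]
  z <- aline_depth_mm(aline, refr_index)[idx]
  keep <- I[idx] > 0
  if (sum(keep) < 5) stop("fewer than 5 positive samples in fit range")
  y <- log(I[idx][keep])
  z <- z[keep]
  fit <- stats::lm.fit(cbind(1, z), y)
  slope <- fit$coefficients[2]
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst <= .Machine$double.eps * length(y)) 1 else max(0, 1 - ssr / sst)
  structure(list(mu_t_per_mm = unname(-slope / 2), slope = unname(slope),
                 intercept_log = unname(fit$coefficients[1]),
                 fit_range = fit_range, r_squared = r2, n_used = sum(keep),
                 layer = layer, negative_flag = unname(-slope / 2) < 0),
            class = "vf_attenfit")
}

# Per-segment SSE of a straight-line fit from cumulative sums, O(1) lookup.
make_seg_sse <- function(z, y) {
  cx <- cumsum(c(0, z)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, z^2)); cxy <- cumsum(c(0, z * y)); cyy <- cumsum(c(0, y^2))
  function(i, j) {
    n <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
    syy <- cyy[j + 1] - cyy[i]
    vxx <- sxx - sx^2 / n
    vyy <- syy - sy^2 / n
    if (vxx <= 0) return(vyy)
    b <- (sxy - sx * sy / n) / vxx
    max(vyy - b^2 * vxx, 0)
  }
}

#' Segment an A-line into layers of distinct attenuation
#'
#' Exact least-squares changepoint segmentation of the log A-line into
#' `n_layers` contiguous segments, each fitted by its own straight line in
#' `ln(I)` vs physical depth: dynamic programming over all breakpoint
#' placements minimizing the total squared error, with a minimum segment
#' length. The length of each distinct attenuation profile gives the layer
#' thickness (physical, via [path_to_depth()]).
#'
#' @param aline a `vf_aline`.
#' @param n_layers number of layers; default 3 (SLP, MID, DEEP).
#' @param min_seg minimum samples per segment; default 5.
#' @param fit_range sample index range to segment; default the full profile.
#' @param refr_index tissue refractive index; default 1.384.
#' @return A list of class `vf_layerseg`: `breakpoints` (global sample
#'   indices of the last sample of each segment but the final one), `fits`
#'   (list of `vf_attenfit`, one per layer), `thickness_um_physical`,
#'   `total_sse`.
#' @export
segment_layers <- function(aline, n_layers = 3, min_seg = 5, fit_range = NULL,
                           refr_index = 1.384) {
  I <- aline$intensity
  if (is.null(fit_range)) fit_range <- c(aline$surface_index, length(I))
  idx <- fit_range[1]:fit_range[2]
  pos <- I[idx] > 0
  idx <- idx[pos]
  L <- length(idx)
  if (L < n_layers * min_seg) stop("too few samples for the requested segmentation")
  z <- aline_depth_mm(aline, refr_index)[idx]
  y <- log(I[idx])
  sse <- make_seg_sse(z, y)
  # dp[k, j]: min total SSE of splitting samples 1..j into k segments
  dp <- matrix(Inf, n_layers, L)
  choice <- matrix(NA_integer_, n_layers, L)
  for (j in min_seg:L) dp[1, j] <- sse(1, j)
  if (n_layers > 1) {
    for (k in 2:n_layers) {
      for (j in (k * min_seg):L) {
        best <- Inf; bi <- NA_integer_
        for (i in ((k - 1) * min_seg):(j - min_seg)) {
          v <- dp[k - 1, i] + sse(i + 1, j)
          if (v < best) { best <- v; bi <- i }
        }
        dp[k, j] <- best; choice[k, j] <- bi
      }
    }
  }
  # backtrack segment ends (local indices)
  ends <- integer(n_layers)
  ends[n_layers] <- L
  if (n_layers > 1)
    for (k in n_layers:2) ends[k - 1] <- choice[k, ends[k]]
  starts <- c(1, utils::head(ends, -1) + 1)
  fits <- lapply(seq_len(n_layers), function(k)
    fit_attenuation(aline, fit_range = c(idx[starts[k]], idx[ends[k]]),
                    refr_index = refr_index))
  thick <- vapply(seq_len(n_layers), function(k) {
    path_to_depth((ends[k] - starts[k] + 1) * aline$step_um_optical,
                  aline$path_angle_deg, refr_index)
  }, numeric(1))
  structure(list(breakpoints = idx[ends[-n_layers]], fits = fits,
                 thickness_um_physical = thick, total_sse = dp[n_layers, L]),
            class = "vf_layerseg")
}
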