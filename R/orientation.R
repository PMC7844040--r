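# Structure-tensor fiber orientation and anisotropy.
#
# Conventions: the image row index increases downward; orientation angles
# are measured in the (col, -row) frame so counterclockwise is positive and
# fibers parallel to the image horizontal (the epithelium surface) have
# theta = 0. With gradients taken along columns (jxx) and rows (jyy), the
# half-angle formula theta = 1/2 * atan2(2*jxy, jyy - jxx) returns the fiber
# direction directly in this convention.

#' Cubic-spline image gradients
#'
#' Partial derivatives of a window along columns (`gx`) and rows (`gy`),
#' computed as analytic derivatives of interpolating cubic splines fitted to
#' each row and column respectively (Forsythe-Malcolm-Moler end conditions,
#' exact for polynomial intensity profiles up to cubic).
#'
#' @param window numeric matrix, at least 8x8.
#' @return A list with matrices `gx` (d/dcol) and `gy` (d/drow).
#' @export
spline_gradients <- function(window) {
  nr <- nrow(window); nc <- ncol(window)
  if (nr < 8 || nc < 8) stop("window must be at least 8x8")
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  xs <- seq_len(nc); ys <- seq_len(nr)
  for (i in seq_len(nr)) {
    row <- window[i, ]
    if (diff(range(row)) > 0)
      gx[i, ] <- stats::splinefun(xs, row, method = "fmm")(xs, deriv = 1)
  }
  for (j in seq_len(nc)) {
    col <- window[, j]
    if (diff(range(col)) > 0)
      gy[, j] <- stats::splinefun(ys, col, method = "fmm")(ys, deriv = 1)
  }
  list(gx = gx, gy = gy)
}

# Cached separable Gaussian smoothing operators (reflective boundaries,
# kernel truncated at 3 sigma).
.smooth_cache <- new.env(parent = emptyenv())

smoothing_matrix <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  if (!is.null(.smooth_cache[[key]])) return(.smooth_cache[[key]])
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-r):r
    idx <- ifelse(idx < 1, 2 - idx, idx)
    idx <- ifelse(idx > n, 2 * n - idx, idx)
    for (t in seq_along(idx)) S[i, idx[t]] <- S[i, idx[t]] + k[t]
  }
  .smooth_cache[[key]] <- S
  S
}

#' Gaussian smoothing of a matrix
#'
#' Separable Gaussian convolution with standard deviation `sigma_px`,
#' truncated at 3 sigma, reflective boundary handling.
#'
#' @param mat numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels.
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  Sr <- smoothing_matrix(nrow(mat), sigma_px)
  Sc <- smoothing_matrix(ncol(mat), sigma_px)
  Sr %*% mat %*% t(Sc)
}

#' Windowed structure tensor
#'
#' Forms the second-moment (structure) tensor of a window: the spline
#' gradient products gx^2, gx*gy, gy^2 are each convolved with a Gaussian
#' kernel of standard deviation `sigma_px` and then averaged over the window
#' to one symmetric 2x2 matrix.
#'
#' @param window numeric matrix (one analysis window).
#' @param sigma_px Gaussian kernel standard deviation; default 2 px, chosen
#'   to match fiber diameters of a few pixels.
#' @return A list of class `vf_tensor`: `jxx`, `jxy`, `jyy`, `sigma_px`.
#' @export
structure_tensor <- function(window, sigma_px = 2) {
  g <- spline_gradients(window)
  jxx <- mean(gaussian_smooth(g$gx * g$gx, sigma_px))
  jxy <- mean(gaussian_smooth(g$gx * g$gy, sigma_px))
  jyy <- mean(gaussian_smooth(g$gy * g$gy, sigma_px))
  structure(list(jxx = jxx, jxy = jxy, jyy = jyy, sigma_px = sigma_px),
            class = "vf_tensor")
}

tensor_eigen <- function(t) {
  tr <- t$jxx + t$jyy
  disc <- sqrt((t$jxx - t$jyy)^2 + 4 * t$jxy^2)
  c(lambda_max = (tr + disc) / 2, lambda_min = (tr - disc) / 2)
}

#' Principal (fiber) orientation from a structure tensor
#'
#' `theta = 1/2 * atan2(2*jxy, jyy - jxx)` in degrees, mapped to (-90, 90],
#' counterclockwise positive relative to the image horizontal. Fibers
#' running parallel to the horizontal give theta = 0. Invariant to intensity
#' scaling. An all-zero tensor (constant window) has no defined orientation
#' and returns `NA`.
#'
#' @param t a `vf_tensor`.
#' @return Orientation in degrees, or `NA_real_` if undefined.
#' @export
principal_orientation <- function(t) {
  if (t$jxx + t$jyy <= 0) return(NA_real_)
  th <- 0.5 * atan2(2 * t$jxy, t$jyy - t$jxx) * 180 / pi
  if (th <= -90) th <- th + 180
  if (th > 90) th <- th - 180
  th
}

#' Anisotropy (coherence) of a structure tensor
#'
#' `A = (lambda_max - lambda_min) / (lambda_max + lambda_min)`,
#' dimensionless in [0, 1]: 1 when all gradient energy lies along one
#' direction (perfectly oriented fibers), 0 for an isotropic distribution.
#' Returns `NA` for a zero tensor.
#'
#' @param t a `vf_tensor`.
#' @return Anisotropy in [0, 1], or `NA_real_`.
#' @export
anisotropy <- function(t) {
  tr <- t$jxx + t$jyy
  if (tr <= 0) return(NA_real_)
  min(sqrt((t$jxx - t$jyy)^2 + 4 * t$jxy^2) / tr, 1)
}

#' Per-window orientation and anisotropy over a whole image
#'
#' Tiles the image into windows ([tile_windows()]), converts to 8-bit
#' grayscale, and computes one structure-tensor orientation/anisotropy pair
#' per window.
#'
#' @param image a `vf_image` or matrix.
#' @param window_px,gap_px windowing parameters; defaults 50 and 5.
#' @param sigma_px Gaussian kernel standard deviation; default 2.
#' @param to_8bit convert to 8-bit grayscale first (default TRUE).
#' @return data.frame with columns `origin_row`, `origin_col`, `theta_deg`,
#'   `anisotropy`, `lambda_max`, `lambda_min`, `flag` (TRUE when the window
#'   is degenerate and orientation undefined).
#' @export
orient_windows <- function(image, window_px = 50, gap_px = 5, sigma_px = 2,
                           to_8bit = TRUE) {
  px <- if (to_8bit) convert_8bit(image) else as_pixels(image)
  grid <- tile_windows(px, window_px, gap_px)
  n <- nrow(grid)
  out <- data.frame(origin_row = grid$origin_row, origin_col = grid$origin_col,
                    theta_deg = NA_real_, anisotropy = NA_real_,
                    lambda_max = NA_real_, lambda_min = NA_real_,
                    flag = logical(max(n, 0)))
  for (i in seq_len(n)) {
    w <- window_at(px, grid$origin_row[i], grid$origin_col[i], window_px)
    t <- structure_tensor(w, sigma_px)
    ev <- tensor_eigen(t)
    out$theta_deg[i] <- principal_orientation(t)
    out$anisotropy[i] <- anisotropy(t)
    out$lambda_max[i] <- ev[["lambda_max"]]
    out$lambda_min[i] <- max(ev[["lambda_min"]], 0)
    out$flag[i] <- is.na(out$theta_deg[i])
  }
  out
}

# Wrap axial angle differences into (-90, 90].
wrap180 <- function(x) {
  y <- (x + 90) %% 180 - 90
  ifelse(y == -90, 90, y)
}

#' Aggregate per-window orientation results over a region
#'
#' Mean and standard deviation of orientation and anisotropy over the
#' windows of one region of interest. Orientations are axial (period 180
#' degrees), so windows are first centered on the circular mean of the
#' doubled angles and deviations wrapped into (-90, 90] before the
#' arithmetic mean and SD are taken; this keeps regions straddling the
#' +/-90 degree wrap well-defined. Flagged (degenerate) windows are
#' excluded and counted.
#'
#' @param results data.frame from [orient_windows()].
#' @param region optional region label to record.
#' @return One-row data.frame: `region`, `n_windows`, `n_flagged`,
#'   `mean_theta_deg`, `sd_theta_deg`, `mean_anisotropy`, `sd_anisotropy`.
#' @export
aggregate_region <- function(results, region = NA_character_) {
  ok <- !results$flag & !is.na(results$theta_deg)
  if (!any(ok)) {
    warning("no valid windows in region")
    return(data.frame(region = region, n_windows = 0L,
                      n_flagged = nrow(results),
                      mean_theta_deg = NA_real_, sd_theta_deg = NA_real_,
                      mean_anisotropy = NA_real_, sd_anisotropy = NA_real_))
  }
  th <- results$theta_deg[ok]
  a <- results$anisotropy[ok]
  rad2 <- th * pi / 90  # doubled angle in radians
  center <- atan2(mean(sin(rad2)), mean(cos(rad2))) * 90 / pi
  dev <- wrap180(th - center)
  mth <- wrap180(center + mean(dev))
  sdth <- if (length(dev) > 1) stats::sd(dev) else 0
  data.frame(region = region, n_windows = sum(ok), n_flagged = sum(!ok),
             mean_theta_deg = mth, sd_theta_deg = sdth,
             mean_anisotropy = mean(a),
             sd_anisotropy = if (sum(ok) > 1) stats::sd(a) else 0)
}
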