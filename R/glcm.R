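# Gray-level co-occurrence matrices and the three Haralick features used to
# characterize collagen texture: contrast (heterogeneity), entropy
# (randomness) and inverse difference moment (homogeneity).

glcm_offset <- function(d_px, angle_deg) {
  # displacement (drow, dcol) for pairs (d*cos(theta), -d*sin(theta)) in the
  # (col, -row) frame: angle 0 is to the right, 45 up-right, 90 up, 135 up-left
  switch(as.character(angle_deg),
         "0"   = c(0, d_px),
         "45"  = c(-d_px, d_px),
         "90"  = c(-d_px, 0),
         "135" = c(-d_px, -d_px),
         stop("angle_deg must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Joint probability `P(i, j)` of gray-level pairs at a fixed pixel
#' displacement: distance `d_px` (1 or 2) along one of the four directions
#' 0, 45, 90, 135 degrees. Ordered-pair counts are symmetrized by adding the
#' transpose and normalized to sum to one.
#'
#' @param qwindow integer matrix of quantized gray levels in
#'   `[0, levels-1]` (see [quantize_gray()]).
#' @param d_px offset distance in pixels (1 or 2).
#' @param angle_deg direction: 0, 45, 90 or 135.
#' @param levels number of gray levels; default `max(qwindow) + 1` rounded
#'   up to at least 2.
#' @return A `levels` x `levels` matrix of class `vf_glcm` with attributes
#'   `d_px` and `angle_deg`.
#' @export
glcm <- function(qwindow, d_px = 1, angle_deg = 0, levels = NULL) {
  if (!d_px %in% c(1, 2)) stop("d_px must be 1 or 2")
  if (is.null(levels)) levels <- max(2L, max(qwindow) + 1L)
  off <- glcm_offset(d_px, angle_deg)
  nr <- nrow(qwindow); nc <- ncol(qwindow)
  if (nr <= abs(off[1]) || nc <= abs(off[2]))
    stop("window smaller than the requested displacement")
  r1 <- max(1, 1 - off[1]):min(nr, nr - off[1])
  c1 <- max(1, 1 - off[2]):min(nc, nc - off[2])
  a <- qwindow[r1, c1, drop = FALSE]
  b <- qwindow[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- matrix(tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  p <- counts + t(counts)
  p <- p / sum(p)
  structure(p, class = c("vf_glcm", "matrix"), d_px = d_px, angle_deg = angle_deg)
}

#' Haralick features of a co-occurrence matrix
#'
#' Three second-order statistics of a normalized GLCM `p(i, j)`:
#' * contrast: `sum((i-j)^2 * p) / (levels-1)^2`, normalized to [0, 1];
#' * entropy: `-sum(p * log(p))` over nonzero cells, in bits by default;
#' * inverse difference moment: `sum(p / (1 + (i-j)^2))`, in (0, 1].
#'
#' @param P a normalized GLCM (matrix).
#' @param base logarithm base for entropy; default 2 (bits).
#' @return Named numeric vector `c(contrast, entropy, idm)`.
#' @export
haralick_features <- function(P, base = 2) {
  L <- nrow(P)
  i <- matrix(rep(seq_len(L) - 1, L), L, L)
  j <- t(i)
  d2 <- (i - j)^2
  contrast <- if (L > 1) sum(d2 * P) / (L - 1)^2 else 0
  nz <- P > 0
  entropy <- -sum(P[nz] * log(P[nz], base = base))
  idm <- sum(P / (1 + d2))
  c(contrast = contrast, entropy = entropy, idm = idm)
}

#' Texture features of one analysis window
#'
#' Quantizes the window, computes the GLCM for every combination of offset
#' distance and direction (8 by default: d in {1, 2} x angles
#' {0, 45, 90, 135}), derives contrast/entropy/IDM from each, and averages
#' the 8 feature triples into a single value characterizing the window.
#' A constant window has no texture and returns the degenerate triple
#' (contrast 0, entropy 0, IDM 1), flagged.
#'
#' @param window numeric matrix (raw intensities), at least 3x3.
#' @param levels gray levels for quantization; default 8.
#' @param d_px offset distances; default `c(1, 2)`.
#' @param angles directions in degrees; default `c(0, 45, 90, 135)`.
#' @param base entropy logarithm base; default 2 (bits).
#' @return One-row data.frame: `contrast`, `entropy`, `idm`,
#'   `n_offsets_averaged`, `flag`.
#' @export
window_texture <- function(window, levels = 8, d_px = c(1, 2),
                           angles = c(0, 45, 90, 135), base = 2) {
  if (nrow(window) < 3 || ncol(window) < 3) stop("window must be at least 3x3")
  if (diff(range(window)) == 0) {
    return(data.frame(contrast = 0, entropy = 0, idm = 1,
                      n_offsets_averaged = length(d_px) * length(angles),
                      flag = TRUE))
  }
  q <- quantize_gray(window, levels)
  feats <- vapply(d_px, function(d) {
    rowMeans(vapply(angles, function(a)
      haralick_features(glcm(q, d, a, levels = levels), base = base),
      numeric(3)))
  }, numeric(3))
  f <- rowMeans(feats)
  data.frame(contrast = f[["contrast"]], entropy = f[["entropy"]],
             idm = f[["idm"]],
             n_offsets_averaged = length(d_px) * length(angles), flag = FALSE)
}

#' Per-window texture features over a whole image
#'
#' Tiles the image ([tile_windows()]) and computes averaged GLCM features
#' per window. OCT frame stacks should be averaged ([average_frames()])
#' before texture analysis.
#'
#' @inheritParams orient_windows
#' @param levels gray levels; default 8 (per-window min-max quantization).
#' @param base entropy logarithm base; default 2.
#' @return data.frame: `origin_row`, `origin_col`, `contrast`,
#'   `entropy`, `idm`, `flag`.
#' @export
texture_windows <- function(image, window_px = 50, gap_px = 5, levels = 8,
                            base = 2) {
  px <- as_pixels(image)
  grid <- tile_windows(px, window_px, gap_px)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    w <- window_at(px, grid$origin_row[i], grid$origin_col[i], window_px)
    window_texture(w, levels = levels, base = base)
  })
  cbind(grid, do.call(rbind, res))
}
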