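# Seeded phantom generators. Every generator is a pure function of its spec
# (including the seed): RNG state is saved and restored, and sub-stages draw
# from stage-specific seeds derived from the master seed so that, e.g.,
# adding noise does not change fiber placement.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Stage-specific sub-seed, kept below 2^31.
sub_seed <- function(seed, stage) (as.numeric(seed) * 7 + stage * 104729) %% 2147483647

#' Specify an SHG fiber phantom
#'
#' Parameters of a synthetic fibrillar collagen image: straight-to-wavy
#' fibers with Gaussian cross-section at a dominant orientation, optional
#' elliptical fenestrations (voids) and additive noise. Defaults emulate
#' the imaging geometry the pipeline targets: ~440 um field of view on a
#' 1024-px grid (0.43 um/px) and fiber diameters of a few micrometers.
#'
#' @param size_px image size `c(rows, cols)`.
#' @param theta_deg dominant fiber orientation in degrees, counterclockwise
#'   positive from the image horizontal, in (-90, 90].
#' @param n_fibers number of fiber centerlines.
#' @param diameter_um full width at half maximum of the Gaussian fiber
#'   cross-section, micrometers.
#' @param wav_period_um,wav_amp_um waviness spatial period and amplitude of
#'   the quasi-sinusoidal centerline, micrometers; `wav_amp_um = 0` gives
#'   straight fibers.
#' @param fenestration_frac target void fraction in [0, 1).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; fiber peak amplitude is `amplitude`).
#' @param pixel_pitch_um micrometers per pixel (isotropic).
#' @param amplitude peak intensity of a single fiber.
#' @param seed integer seed; identical specs give identical phantoms.
#' @return A `fiber_phantom_spec` list.
#' @export
fiber_phantom_spec <- function(size_px = c(300, 300), theta_deg = 0,
                               n_fibers = 60, diameter_um = 2.1,
                               wav_period_um = 18, wav_amp_um = 0,
                               fenestration_frac = 0, noise_sd = 0,
                               pixel_pitch_um = 0.43, amplitude = 200,
                               seed = 1) {
  if (fenestration_frac < 0 || fenestration_frac >= 1)
    stop("fenestration_frac must be in [0, 1)")
  if (diameter_um <= 0) stop("diameter_um must be positive")
  if (wav_amp_um > 0 && wav_period_um <= 2 * pixel_pitch_um)
    stop("wav_period_um must exceed 2 * pixel_pitch_um when waviness is enabled")
  structure(list(size_px = size_px, theta_deg = theta_deg, n_fibers = n_fibers,
                 diameter_um = diameter_um, wav_period_um = wav_period_um,
                 wav_amp_um = wav_amp_um, fenestration_frac = fenestration_frac,
                 noise_sd = noise_sd, pixel_pitch_um = pixel_pitch_um,
                 amplitude = amplitude, seed = seed),
            class = "fiber_phantom_spec")
}

#' Generate an SHG-like fiber phantom with ground truth
#'
#' Renders `n_fibers` ridges with Gaussian cross-section of the specified
#' FWHM. Centerlines follow `v(u) = c + a*sin(2*pi*(u - phase)/lambda)` in a
#' coordinate frame rotated by `theta_deg`, so a phantom at angle phi is, by
#' construction, the 0-degree phantom rotated by phi. Fenestrations are
#' zeroed elliptical holes (random axes, aspect <= 3) added until the void
#' fraction reaches the target to within one percentage point. Contributions
#' of overlapping fibers add; additive Gaussian noise is clamped at zero.
#'
#' @param spec a [fiber_phantom_spec()].
#' @return A list with elements `image` (a `vf_image`, channel "SHG") and
#'   `truth` (spec, logical `fiber_mask` and `fenestration_mask`, realized
#'   `void_frac`).
#' @export
make_fiber_phantom <- function(spec) {
  stopifnot(inherits(spec, "fiber_phantom_spec"))
  nr <- spec$size_px[1]; nc <- spec$size_px[2]
  pitch <- spec$pixel_pitch_um
  sig_px <- spec$diameter_um / pitch / (2 * sqrt(2 * log(2)))
  th <- spec$theta_deg * pi / 180
  # (x, y-up) frame: x = col, y = -row; u along fibers, v across.
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(-seq_len(nr), nc), nr, nc)
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  vr <- range(v)
  lam_px <- spec$wav_period_um / pitch
  amp_px <- spec$wav_amp_um / pitch

  img <- with_seed(sub_seed(spec$seed, 1), {
    centers <- runif(spec$n_fibers, vr[1] - 3 * sig_px, vr[2] + 3 * sig_px)
    phases <- runif(spec$n_fibers, 0, lam_px)
    acc <- matrix(0, nr, nc)
    for (i in seq_len(spec$n_fibers)) {
      vc <- if (amp_px > 0) centers[i] + amp_px * sin(2 * pi * (u - phases[i]) / lam_px)
            else centers[i]
      acc <- acc + spec$amplitude * exp(-(v - vc)^2 / (2 * sig_px^2))
    }
    acc
  })
  fiber_mask <- img >= spec$amplitude / 2

  fen_mask <- matrix(FALSE, nr, nc)
  if (spec$fenestration_frac > 0) {
    fen_mask <- with_seed(sub_seed(spec$seed, 2), {
      m <- matrix(FALSE, nr, nc)
      guard <- 0
      while (mean(m) < spec$fenestration_frac && guard < 100000) {
        guard <- guard + 1
        cr <- runif(1, 1, nr); cc <- runif(1, 1, nc)
        a <- runif(1, 3, 10); b <- a / runif(1, 1, 3)
        ang <- runif(1, 0, pi)
        dx <- x - cc; dy <- -y - cr  # row offset
        e <- ((dx * cos(ang) + dy * sin(ang)) / a)^2 +
             ((-dx * sin(ang) + dy * cos(ang)) / b)^2
        m <- m | (e <= 1)
      }
      m
    })
    img[fen_mask] <- 0
  }

  if (spec$noise_sd > 0) {
    img <- with_seed(sub_seed(spec$seed, 3),
                     pmax(img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc), 0))
  }

  list(image = vf_image(img, bit_depth = 16L, channel = "SHG",
                        pixel_pitch_x_um = pitch, pixel_pitch_z_um = pitch),
       truth = list(spec = spec, fiber_mask = fiber_mask,
                    fenestration_mask = fen_mask, void_frac = mean(fen_mask)))
}

#' Specify a layered OCT B-scan phantom
#'
#' Parameters of a synthetic B-scan frame stack: a flat detectable surface,
#' laterally homogeneous layers that each attenuate the signal exponentially
#' with physical depth at their own total attenuation coefficient, optional
#' multiplicative exponential speckle (unit mean, i.i.d. per pixel per
#' frame), and repeated frames for averaging. Layer thicknesses are physical
#' micrometers; the axial pixel pitch is optical and is converted to physical
#' depth through the refractive index.
#'
#' @param size_px B-scan size `c(rows, cols)` (rows = depth samples).
#' @param n_frames number of consecutive frames; default 5, the count used
#'   for speckle-reduction averaging.
#' @param surface_row row index of the tissue surface.
#' @param layers data.frame with columns `thickness_um` (physical) and
#'   `mu_t_per_mm`; the last layer extends to the bottom of the scan.
#' @param I0 signal amplitude at the surface.
#' @param speckle `"none"` or `"exponential"`.
#' @param refr_index tissue group refractive index; default 1.384.
#' @param pixel_pitch_z_um optical axial pitch, um/px.
#' @param pixel_pitch_x_um lateral pitch, um/px.
#' @param air_noise_sd detector noise above the surface (Gaussian,
#'   magnitude), as a fraction of `I0`.
#' @param seed integer seed.
#' @return An `oct_phantom_spec` list.
#' @export
oct_phantom_spec <- function(size_px = c(300, 200), n_frames = 5,
                             surface_row = 40,
                             layers = data.frame(
                               thickness_um = c(293.3, 837.6, 653.2),
                               mu_t_per_mm = c(0.31, 0.54, 0.15)),
                             I0 = 100, speckle = c("exponential", "none"),
                             refr_index = 1.384, pixel_pitch_z_um = 4.8,
                             pixel_pitch_x_um = 25, air_noise_sd = 1e-3,
                             seed = 1) {
  speckle <- match.arg(speckle)
  if (any(layers$mu_t_per_mm < 0)) stop("mu_t must be >= 0")
  if (any(layers$thickness_um <= 0)) stop("layer thicknesses must be positive")
  depth_um_phys <- (size_px[1] - surface_row) * pixel_pitch_z_um / refr_index
  if (sum(layers$thickness_um[-nrow(layers)]) > depth_um_phys)
    stop("layer thicknesses exceed imaged depth")
  structure(list(size_px = size_px, n_frames = n_frames,
                 surface_row = surface_row, layers = layers, I0 = I0,
                 speckle = speckle, refr_index = refr_index,
                 pixel_pitch_z_um = pixel_pitch_z_um,
                 pixel_pitch_x_um = pixel_pitch_x_um,
                 air_noise_sd = air_noise_sd, seed = seed),
            class = "oct_phantom_spec")
}

# Noise-free mean A-line of an OCT phantom; z measured per row.
oct_mean_profile <- function(spec) {
  nr <- spec$size_px[1]
  rows <- seq_len(nr)
  depth_opt_um <- pmax(rows - spec$surface_row, 0) * spec$pixel_pitch_z_um
  z_mm <- depth_opt_um / spec$refr_index / 1000
  bounds_mm <- cumsum(spec$layers$thickness_um) / 1000
  mu <- spec$layers$mu_t_per_mm
  # cumulative attenuation integral int_0^z mu dz' (piecewise constant mu;
  # the last layer extends indefinitely)
  cum_at_bound <- cumsum(mu * diff(c(0, bounds_mm)))
  cumint <- function(z) {
    k <- findInterval(z, bounds_mm) + 1
    k <- pmin(k, length(mu))
    lower <- c(0, bounds_mm)[k]
    base <- c(0, cum_at_bound)[k]
    base + mu[k] * (z - lower)
  }
  prof <- spec$I0 * exp(-2 * cumint(z_mm))
  prof[rows < spec$surface_row] <- 0
  list(profile = prof, z_mm = z_mm,
       layer_id = ifelse(rows < spec$surface_row, 0L,
                         pmin(findInterval(z_mm, bounds_mm) + 1L, length(mu))))
}

#' Generate a layered, speckled OCT B-scan frame stack with ground truth
#'
#' The mean depth profile below the surface follows
#' `I0 * exp(-2 * integral of mu_t over physical depth)`, piecewise per
#' layer, so the log A-line is piecewise linear with slope `-2 * mu_t` per
#' physical millimeter. Exponential speckle multiplies each pixel of each
#' frame independently (unit mean), leaving the ensemble mean equal to the
#' noiseless profile. Rows above the surface contain only weak detector
#' noise.
#'
#' @param spec an [oct_phantom_spec()].
#' @return A list with `frames` (a `vf_stack` of `vf_image`s, channel
#'   "OCT") and `truth` (spec, per-row `layer_id` [0 = air], boundary rows,
#'   noiseless `profile`).
#' @export
make_oct_phantom <- function(spec) {
  stopifnot(inherits(spec, "oct_phantom_spec"))
  nr <- spec$size_px[1]; nc <- spec$size_px[2]
  mp <- oct_mean_profile(spec)
  base <- matrix(mp$profile, nr, nc)
  air <- seq_len(nr) < spec$surface_row
  frames <- with_seed(sub_seed(spec$seed, 4), {
    lapply(seq_len(spec$n_frames), function(f) {
      img <- base
      if (spec$speckle == "exponential")
        img <- img * matrix(stats::rexp(nr * nc), nr, nc)
      if (spec$air_noise_sd > 0)
        img[air, ] <- abs(matrix(stats::rnorm(sum(air) * nc, 0,
                                              spec$air_noise_sd * spec$I0),
                                 sum(air), nc))
      vf_image(img, bit_depth = 16L, channel = "OCT",
               pixel_pitch_x_um = spec$pixel_pitch_x_um,
               pixel_pitch_z_um = spec$pixel_pitch_z_um)
    })
  })
  bounds_mm <- cumsum(spec$layers$thickness_um) / 1000
  boundary_rows <- spec$surface_row +
    bounds_mm * 1000 * spec$refr_index / spec$pixel_pitch_z_um
  list(frames = structure(frames, class = "vf_stack"),
       truth = list(spec = spec, layer_id = mp$layer_id,
                    boundary_rows = boundary_rows, profile = mp$profile,
                    z_mm = mp$z_mm))
}

#' Generate an isotropic noise image
#'
#' I.i.d. uniform noise on `[0, max_val]`: no preferred orientation, the
#' null case for the anisotropy measure.
#'
#' @param size_px image size `c(rows, cols)`.
#' @param seed integer seed.
#' @param max_val upper bound of the uniform intensities.
#' @return A `vf_image` (channel "SHG").
#' @export
make_isotropic_noise <- function(size_px, seed = 1, max_val = 255) {
  px <- with_seed(sub_seed(seed, 5),
                  matrix(runif(prod(size_px), 0, max_val), size_px[1], size_px[2]))
  vf_image(px, bit_depth = 8L, channel = "SHG")
}
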