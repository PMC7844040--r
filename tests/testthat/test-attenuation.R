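make_exp_aline <- function(mu, n = 420, step_um = 4.8, angle = 0, I0 = 100,
                           refr_index = 1.384) {
  z_mm <- path_to_depth((seq_len(n) - 1) * step_um, angle, refr_index) / 1000
  structure(list(intensity = I0 * exp(-2 * mu * z_mm), step_um_optical = step_um,
                 path_angle_deg = angle, surface_index = 1L, truncated = FALSE),
            class = "vf_aline")
}

test_that("frame averaging is the pixelwise arithmetic mean", {
  same <- replicate(5, matrix(3, 4, 4), simplify = FALSE)
  expect_equal(average_frames(same, 5), matrix(3, 4, 4))
  alt <- lapply(c(0, 2, 0, 2, 0), function(v) matrix(v, 2, 2))
  expect_equal(average_frames(alt, 5), matrix(0.8, 2, 2))
  expect_error(average_frames(list(matrix(0, 2, 2), matrix(0, 3, 3)), 2),
               "shapes")
  expect_error(average_frames(same, 9), "fewer")
})

test_that("5-frame averaging shrinks speckle noise by about sqrt(5)", {
  spec <- oct_phantom_spec(size_px = c(200, 300), surface_row = 20,
                           layers = data.frame(thickness_um = 500,
                                               mu_t_per_mm = 0.3),
                           speckle = "exponential", seed = 21)
  ph <- make_oct_phantom(spec)
  avg <- average_frames(ph$frames, 5)
  row <- 60  # fixed depth: i.i.d. speckle across columns
  sd1 <- sd(ph$frames[[1]]$pixels[row, ])
  sd5 <- sd(avg$pixels[row, ])
  expect_equal(sd5, sd1 / sqrt(5), tolerance = 0.25)
})

test_that("normalization is scale-invariant and robust to hot pixels", {
  b <- matrix(10, 30, 30)
  expect_true(all(normalize_bscan(b) == 1))
  set.seed(2)
  img <- matrix(runif(10000, 0, 50), 100, 100)
  n1 <- normalize_bscan(img)
  n2 <- normalize_bscan(img * 7.3)
  expect_equal(as.vector(n1), as.vector(n2), tolerance = 1e-12)
  # one hot pixel does not dominate the normalization constant
  img2 <- matrix(1, 100, 100); img2[5, 5] <- 1000
  nn <- normalize_bscan(img2)
  expect_equal(attr(nn, "norm_constant"), 1, tolerance = 0.01)
  expect_error(normalize_bscan(matrix(0, 5, 5)), "all-zero")
})

test_that("surface detection finds flat and tilted phantom surfaces", {
  spec <- oct_phantom_spec(size_px = c(200, 120), surface_row = 40,
                           layers = data.frame(thickness_um = 400,
                                               mu_t_per_mm = 0.3),
                           speckle = "none", seed = 3)
  b <- normalize_bscan(average_frames(make_oct_phantom(spec)$frames, 5))
  s <- detect_surface(b)
  expect_true(all(abs(s$surface - 40) <= 1))
  # tilted surface: shift each column by a linear ramp
  px <- as.matrix(b)
  tilt <- matrix(0, 200, 120)
  shift <- round(seq(0, 30, length.out = 120))
  for (j in 1:120) tilt[(1 + shift[j]):200, j] <- px[1:(200 - shift[j]), j]
  st <- detect_surface(tilt)
  expect_true(all(abs(st$surface - (40 + shift)) <= 2))
  # pure noise: no surface anywhere
  set.seed(9)
  noise <- matrix(abs(rnorm(200 * 50, 0, 1e-3)), 200, 50)
  sn <- detect_surface(noise)
  expect_true(all(sn$flagged))
})

test_that("midline extraction reduces to the raw column at angle 0", {
  spec <- oct_phantom_spec(size_px = c(300, 60), surface_row = 30,
                           layers = data.frame(thickness_um = 800,
                                               mu_t_per_mm = 0.4),
                           speckle = "none", air_noise_sd = 0, seed = 4)
  ph <- make_oct_phantom(spec)
  b <- ph$frames[[1]]$pixels
  al <- extract_midline(b, rep(30L, 60), edge_col = 30, angle_deg = 0,
                        pixel_pitch_z_um = 4.8)
  expect_equal(al$intensity, b[30:300, 30], tolerance = 1e-12,
               ignore_attr = TRUE)
  # first sample sits at the surface maximum
  expect_equal(which.max(al$intensity), 1)
  # 45-degree line on a laterally homogeneous phantom: same profile as the
  # vertical line, stretched by 1/cos(45) in path length
  al45 <- extract_midline(b, rep(30L, 60), edge_col = 5, angle_deg = 45,
                          pixel_pitch_z_um = 4.8)
  k <- 29  # sample index along the 45-degree path
  vert_equiv <- b[30 + round(k * cos(pi / 4)), 5 + round(k * sin(pi / 4))]
  expect_equal(al45$intensity[k + 1], vert_equiv, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(fit_attenuation(al45)$mu_t_per_mm,
               fit_attenuation(al)$mu_t_per_mm, tolerance = 1e-6)
  # lateral averaging over parallel vertical lines = mean of raw columns
  al5 <- extract_midline(b, rep(30L, 60), edge_col = 30, angle_deg = 0,
                         pixel_pitch_z_um = 4.8, n_avg = 5)
  expect_equal(al5$intensity, rowMeans(b[30:300, 28:32]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("attenuation fitting is exact on noiseless exponentials", {
  for (mu in c(0, 0.15, 0.31, 0.54)) {
    f <- fit_attenuation(make_exp_aline(mu))
    expect_equal(f$mu_t_per_mm, mu, tolerance = 1e-9)
    expect_equal(f$slope, -2 * mu, tolerance = 1e-9)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
  expect_false(fit_attenuation(make_exp_aline(0.3))$negative_flag)
  expect_error(fit_attenuation(make_exp_aline(0.3, n = 3)), "fewer than 5")
})

test_that("speckled single-layer recovery is within 5% with 1000-column averaging", {
  spec <- oct_phantom_spec(size_px = c(420, 1000), surface_row = 20,
                           layers = data.frame(thickness_um = 1300,
                                               mu_t_per_mm = 0.54),
                           speckle = "exponential", seed = 31)
  ph <- make_oct_phantom(spec)
  avg <- average_frames(ph$frames, 5)
  prof <- rowMeans(avg$pixels)[20:420]
  al <- structure(list(intensity = prof, step_um_optical = 4.8,
                       path_angle_deg = 0, surface_index = 1L,
                       truncated = FALSE), class = "vf_aline")
  f <- fit_attenuation(al)
  expect_lt(abs(f$mu_t_per_mm - 0.54) / 0.54, 0.05)
})

test_that("changepoint segmentation recovers the 3-layer truth", {
  spec <- oct_phantom_spec(size_px = c(600, 8), surface_row = 30,
                           speckle = "none", air_noise_sd = 0, seed = 5)
  ph <- make_oct_phantom(spec)
  al <- extract_midline(ph$frames[[1]]$pixels, rep(30L, 8), edge_col = 4,
                        angle_deg = 0, pixel_pitch_z_um = 4.8)
  seg <- segment_layers(al, n_layers = 3)
  truth_breaks <- ph$truth$boundary_rows[1:2] - 30 + 1
  expect_true(all(abs(seg$breakpoints - truth_breaks) <= 2))
  mus <- vapply(seg$fits, function(f) f$mu_t_per_mm, numeric(1))
  expect_equal(mus, spec$layers$mu_t_per_mm, tolerance = 0.02)
  # thickness conservation: per-layer thicknesses sum to the full span
  total <- path_to_depth(length(al$intensity) * 4.8, 0, 1.384)
  expect_equal(sum(seg$thickness_um_physical), total, tolerance = 1e-9)
  # recovered thicknesses match truth within 2 samples' worth of microns
  tol_um <- 2 * 4.8 / 1.384
  expect_lt(max(abs(seg$thickness_um_physical[1:2] -
                    spec$layers$thickness_um[1:2])), 2 * tol_um)
})

test_that("single- and two-layer segmentations behave exactly", {
  al <- make_exp_aline(0.3, n = 100)
  seg1 <- segment_layers(al, n_layers = 1)
  expect_length(seg1$breakpoints, 0)
  expect_equal(seg1$fits[[1]]$mu_t_per_mm, 0.3, tolerance = 1e-9)
  # two-slope profile: exact breakpoint on noiseless input
  z <- path_to_depth((0:199) * 4.8, 0, 1.384) / 1000
  y <- ifelse(seq_along(z) <= 100, -2 * 0.2 * z,
              -2 * 0.2 * z[100] - 2 * 0.6 * (z - z[100]))
  al2 <- structure(list(intensity = 100 * exp(y), step_um_optical = 4.8,
                        path_angle_deg = 0, surface_index = 1L,
                        truncated = FALSE), class = "vf_aline")
  seg2 <- segment_layers(al2, n_layers = 2)
  expect_true(abs(seg2$breakpoints - 100) <= 1)
})

test_that("segmentation SSE is minimal against random breakpoint choices", {
  set.seed(17)
  spec <- oct_phantom_spec(size_px = c(300, 40), surface_row = 20,
                           layers = data.frame(
                             thickness_um = c(300, 400, 200),
                             mu_t_per_mm = c(0.31, 0.54, 0.15)),
                           speckle = "exponential", seed = 41)
  ph <- make_oct_phantom(spec)
  prof <- rowMeans(average_frames(ph$frames, 5)$pixels)[20:300]
  al <- structure(list(intensity = prof, step_um_optical = 4.8,
                       path_angle_deg = 0, surface_index = 1L,
                       truncated = FALSE), class = "vf_aline")
  seg <- segment_layers(al, n_layers = 3)
  z <- vfecm:::aline_depth_mm(al)
  y <- log(prof)
  sse_of <- function(b1, b2) {
    segs <- list(1:b1, (b1 + 1):b2, (b2 + 1):length(y))
    sum(vapply(segs, function(ix)
      sum(lm.fit(cbind(1, z[ix]), y[ix])$residuals^2), numeric(1)))
  }
  for (i in 1:20) {
    b1 <- sample(5:(length(y) - 11), 1)
    b2 <- sample((b1 + 5):(length(y) - 5), 1)
    expect_lte(seg$total_sse, sse_of(b1, b2) + 1e-9)
  }
})

test_that("optical path converts to physical depth by cosine and index", {
  expect_equal(path_to_depth(100, 0, 1), 100)
  expect_equal(path_to_depth(100, 45, 1), 100 * sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(path_to_depth(138.4, 0, 1.384), 100, tolerance = 1e-9)
  expect_error(path_to_depth(100, 90), "angle")
  expect_error(path_to_depth(-1, 0), ">= 0")
})

test_that("fit on the 5-frame average matches the mean of single-frame fits", {
  spec <- oct_phantom_spec(size_px = c(400, 600), surface_row = 20,
                           layers = data.frame(thickness_um = 1200,
                                               mu_t_per_mm = 0.4),
                           speckle = "exponential", seed = 51)
  ph <- make_oct_phantom(spec)
  fit_of <- function(m) {
    prof <- rowMeans(m)[20:400]
    al <- structure(list(intensity = prof, step_um_optical = 4.8,
                         path_angle_deg = 0, surface_index = 1L,
                         truncated = FALSE), class = "vf_aline")
    fit_attenuation(al)$mu_t_per_mm
  }
  mu_avg <- fit_of(average_frames(ph$frames, 5)$pixels)
  mu_each <- mean(vapply(1:5, function(i) fit_of(ph$frames[[i]]$pixels),
                         numeric(1)))
  expect_equal(mu_avg, mu_each, tolerance = 0.02)
})
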