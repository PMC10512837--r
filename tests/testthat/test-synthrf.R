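# Synthetic RF generator: reproducibility, PSF linearity, the shift
# theorem, motion-model ground truth, and phantom geometry.

test_that("scatterer scenes are reproducible, contained, and Poisson-sized", {
  region <- c(0, 10, 0, 10)
  s1 <- make_scatterer_field(region, 20, seed = 7)
  s2 <- make_scatterer_field(region, 20, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$axial_mm >= 0 & s1$axial_mm <= 10))
  expect_true(all(s1$lateral_mm >= 0 & s1$lateral_mm <= 10))
  expect_true(all(is.finite(s1$amplitude)))
  # expected count 2000; allow 5 Poisson standard deviations
  expect_lt(abs(length(s1$amplitude) - 2000), 5 * sqrt(2000))
  s3 <- make_scatterer_field(region, 20, seed = 8)
  expect_false(identical(s1$axial_mm, s3$axial_mm))
  expect_error(make_scatterer_field(region, 0), "density")
  expect_error(make_scatterer_field(c(0, 0, 0, 10), 20), "empty")
})

test_that("rendering is linear in scatterer amplitudes", {
  psf <- psf_params()
  base <- make_scatterer_field(c(0, 2, 0, 2), 5, seed = 1)
  one <- base
  one$axial_mm <- 1; one$lateral_mm <- 1; one$amplitude <- 1
  f_one <- render_rf_frame(one, psf)
  # single unit scatterer: frame is the separable PSF kernel
  dz <- mm_per_sample(psf)
  z <- (seq_len(nrow(f_one$samples)) - 1) * dz
  x <- (seq_len(ncol(f_one$samples)) - 1) * psf$pitch
  tau <- 2 * ((z - 1) / 1000) / psf$sound_speed
  gz <- exp(-tau^2 / (2 * psf$axial_pulse_sigma^2)) *
    cos(2 * pi * psf$center_frequency * tau)
  gz[abs(z - 1) > 5 * psf$axial_pulse_sigma * psf$sound_speed * 1000 / 2] <- 0
  gx <- exp(-(x - 1)^2 / (2 * psf$lateral_beam_sigma^2))
  gx[abs(x - 1) > 5 * psf$lateral_beam_sigma] <- 0
  # identical up to the 5-sigma truncation boundary (amplitude ~ 4e-6)
  expect_lt(max(abs(f_one$samples - outer(gz, gx))), 1e-5)

  two <- base
  two$axial_mm <- c(0.4, 1.6); two$lateral_mm <- c(0.4, 1.6)
  two$amplitude <- c(1.3, -0.7)
  p1 <- two; p1$axial_mm <- 0.4; p1$lateral_mm <- 0.4; p1$amplitude <- 1.3
  p2 <- two; p2$axial_mm <- 1.6; p2$lateral_mm <- 1.6; p2$amplitude <- -0.7
  f12 <- render_rf_frame(two, psf)
  fs <- render_rf_frame(p1, psf)$samples + render_rf_frame(p2, psf)$samples
  expect_equal(f12$samples, fs, tolerance = 1e-12)

  dbl <- two; dbl$amplitude <- 2 * two$amplitude
  expect_equal(render_rf_frame(dbl, psf)$samples, 2 * f12$samples,
               tolerance = 1e-12)
})

test_that("integer-sample scene shifts shift the rendered frame", {
  psf <- psf_params()
  dz <- mm_per_sample(psf)
  s <- make_scatterer_field(c(0, 4, 0, 4), 100, seed = 3)
  f1 <- render_rf_frame(s, psf)
  s2 <- warp_scene(s, function(z, x)
    list(d_axial_mm = rep(3 * dz, length(z)),
         d_lateral_mm = rep(0, length(z))))
  f2 <- render_rf_frame(s2, psf, nrow(f1$samples), ncol(f1$samples))
  n <- nrow(f1$samples)
  expect_lt(max(abs(f2$samples[4:n, ] - f1$samples[1:(n - 3), ])),
            1e-6 * max(abs(f1$samples)))
})

test_that("warp evaluates the field at each scatterer position", {
  s <- make_scatterer_field(c(0, 4, 0, 4), 20, seed = 5)
  shift <- function(z, x) list(d_axial_mm = rep(0.3, length(z)),
                               d_lateral_mm = rep(0, length(z)))
  s2 <- warp_scene(s, shift)
  expect_equal(s2$axial_mm, s$axial_mm + 0.3)
  expect_equal(s2$lateral_mm, s$lateral_mm)
  expect_identical(s2$amplitude, s$amplitude)
  back <- warp_scene(s2, function(z, x)
    list(d_axial_mm = rep(-0.3, length(z)), d_lateral_mm = rep(0, length(z))))
  expect_equal(back$axial_mm, s$axial_mm, tolerance = 1e-15)

  lin <- function(z, x) list(d_axial_mm = 0.05 * z,
                             d_lateral_mm = rep(0, length(z)))
  s3 <- s; s3$axial_mm <- c(2, 1); s3$lateral_mm <- c(1, 1)
  s3$amplitude <- c(1, 1)
  w <- warp_scene(s3, lin)
  expect_equal(w$axial_mm, c(2 + 2 * 0.05, 1 + 0.05))
})

test_that("sequences carry consistent analytic ground truth", {
  psf <- psf_params()
  dz <- mm_per_sample(psf)
  s <- make_scatterer_field(c(0, 4, 0, 4), 50, seed = 2)

  m <- motion_model("uniform", n_frames = 5, axial_mm_per_frame = 2 * dz)
  seq <- generate_sequence(s, psf, m)
  expect_length(seq$frames, 5)
  cum <- seq$truth$cumulative(4)(c(1, 2.5), c(0.5, 3))
  expect_equal(cum$d_axial_mm, rep(8 * dz, 2))
  # incremental fields sum to the cumulative field
  inc <- seq$truth$incremental(1)(c(1, 2.5), c(0.5, 3))
  expect_equal(4 * inc$d_axial_mm, cum$d_axial_mm)

  z0 <- generate_sequence(s, psf,
                          motion_model("uniform", n_frames = 2,
                                       axial_mm_per_frame = 0))
  expect_identical(z0$frames[[1]]$samples, z0$frames[[2]]$samples)

  tm <- motion_model("transmural_gradient", n_frames = 3,
                     center = c(0, 0), r_inner = 10, r_outer = 16,
                     epi_total_mm = 0.05, endo_total_mm = 0.35)
  sq <- generate_sequence(make_scatterer_field(c(0, 18, -17, 17), 1, seed = 1),
                          psf, tm, n_axial = 50, n_lines = 50)
  cumfun <- sq$truth$cumulative(2)
  at_endo <- cumfun(10, 0)$d_axial_mm   # rho = r_inner
  at_epi <- cumfun(16, 0)$d_axial_mm    # rho = r_outer
  # endocardial motion exceeds epicardial by the full imposed gradient
  expect_equal(at_endo - at_epi, 0.35 - 0.05, tolerance = 1e-12)

  expect_error(generate_sequence(s, psf,
                                 motion_model("uniform", n_frames = 40,
                                              axial_mm_per_frame = 0.5)),
               "exceeds")
})

test_that("the LV phantom has the stated half-annulus geometry", {
  ph <- make_lv_phantom(c(4, 6), c(6, 8), center = c(1, 0), seed = 1)
  z0 <- 1
  # endo key points strictly inside the epi contour
  norm_epi <- ((ph$endo_keypoints$lateral_mm - 0) / 6)^2 +
    ((ph$endo_keypoints$axial_mm - z0) / 8)^2
  expect_true(all(norm_epi < 1))
  # first/last key points of both borders on the basal line
  expect_equal(ph$endo_keypoints$axial_mm[c(1, 13)], c(z0, z0))
  expect_equal(ph$epi_keypoints$axial_mm[c(1, 13)], c(z0, z0))
  # scatterers confined to the annulus
  nz <- (ph$scene$lateral_mm / 6)^2 + ((ph$scene$axial_mm - z0) / 8)^2
  ni <- (ph$scene$lateral_mm / 4)^2 + ((ph$scene$axial_mm - z0) / 6)^2
  expect_true(all(nz <= 1 + 1e-12))
  expect_true(all(ni >= 1 - 1e-12))
  expect_true(all(ph$scene$axial_mm >= z0))
  # annulus area recovered from the scatterer count within 2%
  area <- pi / 2 * (6 * 8 - 4 * 6)
  expect_lt(abs(length(ph$scene$amplitude) / 200 - area) / area, 0.02)
  expect_error(make_lv_phantom(c(6, 8), c(4, 6)), "inner_axes")
})
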