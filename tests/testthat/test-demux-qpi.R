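test_that("unwrapping recovers smooth ramps and stays congruent mod 2*pi", {
  n <- 96L
  g <- bfdhm:::pixel_grids(c(n, n))
  ramp <- 4 * pi * g$x / (n - 1) + 2.5 * pi * g$y / (n - 1)
  w <- Arg(exp(1i * ramp))
  u <- unwrap_phase(w)
  offs <- (u - ramp)[1, 1]
  expect_lt(max(abs(u - ramp - offs)), 1e-9)           # exact mod global 2*pi
  expect_equal(offs / (2 * pi), round(offs / (2 * pi)), tolerance = 1e-9)
  k <- (u - w) / (2 * pi)
  expect_lt(max(abs(k - round(k))), 1e-9)              # pixelwise congruence
  expect_identical(attr(u, "residues"), 0L)
  expect_error(unwrap_phase(matrix(4, 8, 8)), "wrapped phase")
})

test_that("unwrapping handles a wrapped gaussian bump beyond 2*pi", {
  n <- 128L
  g <- bfdhm:::pixel_grids(c(n, n))
  bump <- 9 * exp(-((g$x - 64)^2 + (g$y - 64)^2) / (2 * 15^2))
  u <- unwrap_phase(Arg(exp(1i * bump)))
  expect_lt(max(abs(u - bump - (u - bump)[1, 1])), 1e-9)
})

test_that("aberration compensation removes its own polynomial class", {
  n <- 128L
  xs <- seq(-1, 1, length.out = n)
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  quad <- 0.8 + 1.2 * X - 0.7 * Y + 2.3 * X^2 + 0.9 * X * Y - 1.1 * Y^2
  out <- compensate_aberrations(quad, matrix(TRUE, n, n), poly_degree = 4)
  expect_lt(sqrt(mean(out^2)), 1e-3)
  # idempotence
  r4 <- (X^2 + Y^2)^2
  once <- compensate_aberrations(quad + r4)
  twice <- compensate_aberrations(once)
  expect_lt(sqrt(mean((twice - once)^2)), 1e-6)
  # mask-size guard
  expect_error(compensate_aberrations(quad, corner_mask(c(n, n), frac = 0.05)),
               "at least 5%")
})

test_that("a known injected spherical surface is recovered over the sphere scene", {
  cfg <- cfg_small(192)
  maps <- phantom_maps(sphere_phantom(cfg), cfg)
  n <- cfg$sensor_shape[1]
  xs <- seq(-1, 1, length.out = n)
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  aberr <- 1.7 * (X^2 + Y^2) - 0.6 * (X^2 + Y^2)^2 + 0.9 * X
  out <- compensate_aberrations(maps$phase + aberr)
  support <- maps$thickness > 0
  resid <- out - maps$phase
  resid <- resid - stats::median(resid[!support])
  expect_lt(sqrt(mean(resid[support]^2)), 0.05)
})

test_that("background subtraction flattens planes and preserves object peaks", {
  n <- 128L
  expect_lt(max(abs(subtract_background(matrix(2.2, n, n)))), 1e-9)
  xs <- seq(-1, 1, length.out = n)
  tilt <- outer(xs * 0.7, xs * -1.3, `+`)
  expect_lt(max(abs(subtract_background(tilt))), 1e-6)
  cfg <- cfg_small(n)
  maps <- phantom_maps(sphere_phantom(cfg), cfg)
  out <- subtract_background(maps$phase)
  expect_equal(max(out), max(maps$phase), tolerance = 1e-3)
})

test_that("phase converts to thickness by phi*lambda/(2 pi dn)", {
  expect_equal(phase_to_thickness(0, 532e-9, 0.05), 0)
  expect_equal(phase_to_thickness(5.905, 532e-9, 0.05), 10, tolerance = 1e-3)
  phi <- matrix(seq(-2, 6, length.out = 12), 3, 4)
  expect_equal(phase_to_thickness(2 * phi, 532e-9, 0.05),
               2 * phase_to_thickness(phi, 532e-9, 0.05))
  expect_error(phase_to_thickness(1, 532e-9, 0), "delta_n")
})

test_that("end-to-end QPI of a noise-free microsphere recovers its thickness", {
  cfg <- cfg_small(384)
  ph <- sphere_phantom(cfg)   # 10 um PMMA sphere in glycerin-water
  # maximum hologram contrast so 8-bit quantization does not dominate
  img <- synthesize_multiplexed(ph, cfg, illumination_setting(2.0, 30),
                                noise_off())
  q <- reconstruct_qpi(img, delta_n = 0.05)
  expect_equal(max(q$thickness), 10, tolerance = 0.03)
  # phase error on the resolvable part of the dome (the outermost ~1 um
  # annulus carries gradients beyond the cross-band passband): compared
  # both against the pupil-limited coherent image (what the optics
  # deliver) and the geometric ground truth, which differs from it by
  # the diffraction ringing of the hard circular pupil
  maps <- phantom_maps(ph, cfg)
  fovc <- field_of_view(cfg) / 2
  ax <- bfdhm:::object_plane_axes(cfg)
  rho <- sqrt(outer((ax$y - fovc[["height"]])^2, rep(1, length(ax$x))) +
                outer(rep(1, length(ax$y)), (ax$x - fovc[["width"]])^2))
  core <- rho <= 0.7 * 5
  optical <- unwrap_phase(Arg(render_object_wave(ph, cfg,
                                                 pupil_cutoff_px = q$cross_radius)))
  optical <- optical - stats::median(optical[rho > 20 & rho < 40])
  expect_lt(sqrt(mean((q$qpi[core] - optical[core])^2)), 0.08)
  expect_lt(sqrt(mean((q$qpi[core] - maps$phase[core])^2)), 0.1)
  # wrapped phase is in range and the background ends near zero
  expect_true(all(q$wrapped <= pi & q$wrapped > -pi))
  rois <- corner_rois(cfg$sensor_shape)
  expect_lt(abs(stats::median(q$qpi[roi_mask(rois, dim(q$qpi))])), 0.05)
})
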