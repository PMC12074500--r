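test_that("object wave of an empty phantom is a uniform unit field", {
  cfg <- cfg_small(64)
  O <- render_object_wave(phantom(), cfg)
  expect_equal(Mod(O), matrix(1, 64, 64), tolerance = 1e-9)
  expect_equal(Arg(O), matrix(0, 64, 64), tolerance = 1e-9)
})

test_that("rendered sphere phase hits the closed-form peak with a wide pupil", {
  cfg <- cfg_small(192)
  ph <- sphere_phantom(cfg)
  O <- render_object_wave(ph, cfg, pupil_cutoff_px = Inf)
  # peak 5.905 rad wraps; compare through the complex field
  maps <- phantom_maps(ph, cfg)
  idx <- which.max(maps$phase)
  expect_equal(Arg(O[idx] * exp(-1i * 5.905)), 0, tolerance = 1e-3)
})

test_that("bright field ignores phase structure and images absorption", {
  cfg <- cfg_small(192)
  # pure phase sphere: deviation from unity below 5%
  bfi <- render_bright_field(sphere_phantom(cfg), cfg)
  expect_lt(max(abs(bfi - 1)), 0.05)
  expect_true(all(bfi >= 0))
  # wide absorbing disk: centre converges to its transmittance
  ph <- sphere_phantom(cfg, radius = 15, transmittance = 0.5)
  bfi2 <- render_bright_field(ph, cfg)
  ctr <- round(dim(bfi2) / 2)
  expect_equal(bfi2[ctr[1], ctr[2]], 0.5, tolerance = 0.01)
  # oracle: direct convolution with the incoherent OTF
  maps <- phantom_maps(ph, cfg)
  pupil <- (function(s) {
    g <- bfdhm:::freq_grids(s)
    (sqrt(g$fx^2 + g$fy^2) <= pupil_cutoffs_px(cfg)[["coherent"]]) * 1
  })(cfg$sensor_shape)
  psf <- Mod(stats::fft(bfdhm:::ifftshift(pupil), inverse = TRUE) /
               length(pupil))^2
  otf <- stats::fft(psf); otf <- otf / otf[1, 1]
  oracle <- Re(stats::fft(stats::fft(maps$amplitude^2) * otf,
                          inverse = TRUE) / length(otf))
  expect_equal(bfi2, pmax(oracle, 0), tolerance = 1e-9)
})

test_that("multiplexed synthesis is deterministic and linear in LED power", {
  cfg <- cfg_small(96)
  ph <- sphere_phantom(cfg, transmittance = 0.9)
  a <- synthesize_multiplexed(ph, cfg, noise = noise_model(seed = 11))
  b <- synthesize_multiplexed(ph, cfg, noise = noise_model(seed = 11))
  expect_identical(a$pixels, b$pixels)
  d <- synthesize_multiplexed(ph, cfg, noise = noise_model(seed = 12))
  expect_false(identical(a$pixels, d$pixels))
  # linearity before quantization, noise off
  il <- function(pl) illumination_setting(p_laser = 0.7, p_led = pl)
  g0 <- synthesize_multiplexed(ph, cfg, il(0), noise_off(), quantize = FALSE)
  bfi <- render_bright_field(ph, cfg)
  for (alpha in c(3, 12, 30)) {
    ga <- synthesize_multiplexed(ph, cfg, il(alpha), noise_off(),
                                 quantize = FALSE)
    delta <- (ga$pixels - g0$pixels) / alpha
    expect_lt(max(abs(delta - 6 * bfi)) / max(6 * bfi), 1e-6)
  }
})

test_that("spectral energy stays inside the incoherent and carrier bands", {
  cfg <- cfg_small(256)
  ph <- sphere_phantom(cfg, transmittance = 0.9)
  img <- synthesize_multiplexed(ph, cfg, illumination_setting(2, 30),
                                noise_off(), quantize = FALSE)
  S <- bfdhm:::fftshift(stats::fft(img$pixels))
  cuts <- pupil_cutoffs_px(cfg)
  fc <- carrier_frequency_px(cfg)
  inside <- bfdhm:::radial_mask(dim(S), c(0, 0), cuts[["incoherent"]]) +
    bfdhm:::radial_mask(dim(S), fc, cuts[["coherent"]]) +
    bfdhm:::radial_mask(dim(S), -fc, cuts[["coherent"]])
  out_frac <- sum(Mod(S[inside == 0])^2) / sum(Mod(S)^2)
  expect_lt(out_frac, 1e-3)
})

test_that("laser-free captures carry no carrier; LED-free captures are pure holograms", {
  cfg <- cfg_small(256)
  off <- synthesize_multiplexed(phantom(), cfg,
                                illumination_setting(p_laser = 0, p_led = 30),
                                noise_model(seed = 3))
  expect_error(locate_carrier(compute_spectrum(off)), "no carrier")
  holo <- synthesize_multiplexed(phantom(), cfg,
                                 illumination_setting(p_laser = 2, p_led = 0),
                                 noise_off())
  car <- locate_carrier(compute_spectrum(holo))
  expect_equal(1 / sqrt(sum(car$f_px^2)), 2.738, tolerance = 0.01)
})

test_that("saturation is reported: warning past 1% clipped, error past full-scale mean", {
  cfg <- cfg_small(96)
  expect_warning(
    synthesize_multiplexed(phantom(), cfg,
                           illumination_setting(p_laser = 2, p_led = 36),
                           noise_off()),
    "saturate")
  expect_error(
    synthesize_multiplexed(phantom(), cfg,
                           illumination_setting(p_laser = 2, p_led = 50),
                           noise_off()),
    "full scale")
})
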