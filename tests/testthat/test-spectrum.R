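test_that("spectrum basics: DC placement, cosine pair, Parseval", {
  n <- 64L
  const <- matrix(3, n, n)
  sp <- compute_spectrum(const)
  dc <- floor(n / 2) + 1L
  expect_equal(sum(Mod(sp$S)^2), Mod(sp$S[dc, dc])^2)  # all energy at DC
  # pure cosine at 8 cycles across puts peaks at +/- f0
  g <- bfdhm:::pixel_grids(c(n, n))
  img <- cos(2 * pi * (8 / n) * g$x)
  spc <- compute_spectrum(img)
  mag <- Mod(spc$S)
  peaks <- which(mag > max(mag) / 2, arr.ind = TRUE)
  expect_setequal(peaks[, "col"] - dc, c(-8L, 8L))
  expect_true(all(peaks[, "row"] == dc))
  # Parseval with the window off
  expect_equal(sum(Mod(spc$S)^2) / n^2, sum(img^2), tolerance = 1e-9)
})

test_that("carrier location recovers the preset tilt and ignores LED power", {
  cfg <- cfg_small(512)
  img <- flat_capture(cfg)
  car <- locate_carrier(compute_spectrum(img))
  expect_equal(car$angle_deg, 1.9, tolerance = 0.05)
  expect_gt(car$ratio, 3)
  # peak position independent of LED power (no carrier in the LED term)
  f3 <- locate_carrier(compute_spectrum(flat_capture(cfg, p_led = 3)))$f_px
  f30 <- locate_carrier(compute_spectrum(flat_capture(cfg, p_led = 30)))$f_px
  expect_lt(sqrt(sum((f3 - f30)^2)), 0.01)
})

test_that("cross-band extraction equals the spatial-domain demodulation oracle", {
  # brute-force oracle: multiply by exp(-2 pi i f.x), low-pass at DC.
  # On a bin-exact carrier both routes are algebraically identical.
  n <- 64L
  fc <- c(10 / n, 7 / n)
  g <- bfdhm:::pixel_grids(c(n, n))
  set.seed(42)
  smooth <- Re(bfdhm:::ifft2(bfdhm:::ifftshift(
    bfdhm:::fftshift(bfdhm:::fft2(matrix(rnorm(n^2), n, n))) *
      bfdhm:::radial_mask(c(n, n), c(0, 0), 0.06))))
  obj <- exp(1i * 3 * smooth / max(abs(smooth)))
  holo <- 4 + Mod(obj)^2 + 2 * Re(obj * exp(2i * pi * (fc[1] * g$x + fc[2] * g$y)))
  radius <- 0.09
  soft <- 0.009
  got <- extract_cross_band(compute_spectrum(holo), fc, radius, soft)
  demod <- holo * exp(-2i * pi * (fc[1] * g$x + fc[2] * g$y))
  oracle <- bfdhm:::ifft2(bfdhm:::ifftshift(
    bfdhm:::fftshift(bfdhm:::fft2(demod)) *
      bfdhm:::radial_mask(c(n, n), c(0, 0), radius, soft)))
  expect_lt(max(Mod(got - oracle)), 1e-6)
})

test_that("flat objects demodulate to flat phase; magnitudes track |O||R|", {
  cfg <- cfg_small(256)
  img <- flat_capture(cfg, quantize = FALSE)
  sp <- compute_spectrum(img$pixels); sp$config <- cfg
  Bc <- extract_cross_band(sp, locate_carrier(sp)$f_px)
  # interior phase flat after removing the residual carrier tilt
  comp <- compensate_aberrations(Arg(Bc), poly_degree = 1)
  interior <- comp[33:224, 33:224]
  expect_lt(sqrt(mean((interior - mean(interior))^2)), 0.01)
  # magnitude proportional to |O||R| for an absorbing, phase-flat phantom
  # (LED off so the bright-field spectrum cannot bleed into the band)
  ph <- sphere_phantom(cfg, radius = 15, ri = 1.43, transmittance = 0.6)
  img2 <- synthesize_multiplexed(ph, cfg, illumination_setting(0.4, 0),
                                 noise_off(), quantize = FALSE,
                                 keep_truth = TRUE)
  sp2 <- compute_spectrum(img2$pixels); sp2$config <- cfg
  B2 <- Mod(extract_cross_band(sp2, locate_carrier(sp2)$f_px))
  expect_gt(stats::cor(as.vector(B2), as.vector(Mod(img2$truth$O))), 0.99)
})

test_that("central band reproduces laser-free bright field and guards overlap", {
  cfg <- cfg_small(256)
  ph <- sphere_phantom(cfg, radius = 12, transmittance = 0.7)
  img <- synthesize_multiplexed(ph, cfg,
                                illumination_setting(p_laser = 0, p_led = 30),
                                noise_off(), keep_truth = TRUE)
  sp <- compute_spectrum(img$pixels)
  A <- extract_central_band(sp, radius = 0.18)
  expect_gt(stats::cor(as.vector(A), as.vector(img$truth$bfi)), 0.999)
  # constant image -> constant band magnitude
  Ac <- extract_central_band(compute_spectrum(matrix(7, 64, 64)), 0.2)
  expect_equal(Ac, matrix(7, 64, 64), tolerance = 1e-9)
  # a radius bleeding into the cross band is refused
  fc <- carrier_frequency_px(cfg)
  expect_error(
    extract_central_band(sp, radius = 0.3, carrier = fc, cross_radius = 0.18),
    "overlaps")
})
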