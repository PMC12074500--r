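test_that("weighted subtraction follows BFI = |A| - w B with clipping", {
  A <- matrix(runif(64, 1, 4), 8, 8)
  B <- matrix(runif(64, 0, 2), 8, 8)
  expect_equal(weighted_subtract(A, B, 0), A)       # w = 0: unsubtracted
  expect_equal(weighted_subtract(A, A, 1), A * 0)   # A = B, w = 1: zero image
  expect_true(all(weighted_subtract(B, A, 1) >= 0)) # clipped at zero
  expect_error(weighted_subtract(A, matrix(1, 4, 4), 0.5), "shape")
  expect_error(weighted_subtract(A, B, 1.2), "w must lie")
})

test_that("background STD is the population STD over the ROI union", {
  rois <- background_rois(data.frame(row = 1, col = 1, height = 8, width = 8))
  expect_equal(background_std(matrix(5, 8, 8), rois), 0)
  checker <- matrix(c(0, 2), 8, 8)                  # two-value {0,2} -> 1
  expect_equal(background_std(checker, rois), 1)
  # recovers a generator sigma of 2.6 gray levels
  set.seed(99)
  noisy <- matrix(stats::rnorm(512 * 512, 100, 2.6), 512, 512)
  expect_equal(background_std(noisy, corner_rois(c(512L, 512L))), 2.6,
               tolerance = 0.1 / 2.6)
})

test_that("weight optimization finds exact cancellation and breaks ties low", {
  set.seed(7)
  n <- 64L
  rois <- background_rois(data.frame(row = 5, col = 5, height = 56, width = 56))
  B <- matrix(stats::rnorm(n^2, 10, 2), n, n)
  # B = 0 everywhere: constant curve, tie-break at the smallest w
  flat <- optimize_w(B, B * 0, rois)
  expect_equal(flat$w_opt, 0)
  expect_equal(diff(range(flat$std_curve$std)), 0)
  # A = const + c*B on the ROIs: w_opt lands on the grid point nearest c
  for (c0 in c(0.12, 0.3, 0.62)) {
    A <- 20 + c0 * B
    opt <- optimize_w(A, B, rois)
    expect_equal(opt$w_opt, round(c0 / 0.05) * 0.05, tolerance = 1e-9)
  }
  expect_error(optimize_w(B, B, rois, grid = c(0, 1)), "at least 3")
})

test_that("scale equivariance: k*(A,B) scales the curve by k, w_opt fixed", {
  set.seed(8)
  n <- 64L
  rois <- background_rois(data.frame(row = 5, col = 5, height = 56, width = 56))
  B <- matrix(stats::rnorm(n^2, 10, 2), n, n)
  A <- 25 + 0.4 * B + matrix(stats::rnorm(n^2, 0, 0.5), n, n)
  o1 <- optimize_w(A, B, rois)
  o2 <- optimize_w(3.7 * A, 3.7 * B, rois)
  expect_equal(o2$w_opt, o1$w_opt)
  expect_equal(o2$std_curve$std, 3.7 * o1$std_curve$std, tolerance = 1e-9)
})

test_that("central-band oracle: |A| matches the low-passed ground-truth terms", {
  cfg <- cfg_small(256)
  ph <- sphere_phantom(cfg, transmittance = 0.9)
  img <- synthesize_multiplexed(ph, cfg, illumination_setting(1.0, 30),
                                noise_off(), quantize = FALSE,
                                keep_truth = TRUE)
  sp <- compute_spectrum(img$pixels); sp$config <- cfg
  car <- locate_carrier(sp)
  radius <- min(pupil_cutoffs_px(cfg)[["coherent"]],
                0.5 * sqrt(sum(car$f_px^2)))
  A <- extract_central_band(sp, radius)
  # term-by-term oracle from the simulator ground truth: the fringe-free
  # image content low-passed by the same mask
  f <- img$illumination$laser_ref_fraction
  O <- sqrt(1 - f) * img$truth$O
  base <- 6 * 30 * img$truth$bfi + 18 * 1.0 * (Mod(O)^2 + f)
  oracle <- Mod(bfdhm:::filter_band(compute_spectrum(base), c(0, 0),
                                    radius, 0.1 * radius, FALSE))
  # the bound is set by DFT boundary leakage of the non-integer carrier,
  # a few percent of the fringe amplitude
  fringe_amp <- 18 * 1.0 * 2 * sqrt(f * (1 - f))
  expect_lt(max(abs(A - oracle)), 0.05 * fringe_amp)
})

test_that("recovered BF is quieter than the laser-only intensity on shared ROIs", {
  cfg <- cfg_small(256)
  ph <- sphere_phantom(cfg, transmittance = 0.9)
  rois <- corner_rois(cfg$sensor_shape)
  for (pl in c(0.4, 1.0, 2.0)) {
    img <- synthesize_multiplexed(ph, cfg, illumination_setting(pl, 30),
                                  noise_model(seed = 21))
    bf <- reconstruct_bf(img, rois = rois)
    norm_std <- function(m) 180 * background_std(m, rois) /
      mean(m[roi_mask(rois, dim(m))])
    expect_lt(norm_std(bf$bfi), norm_std(bf$B_mag))
    expect_true(all(bf$bfi >= 0))
    expect_equal(bf$w_opt,
                 bf$std_curve$w[which.min(bf$std_curve$std)])
  }
})
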