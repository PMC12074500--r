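#' Illumination settings for a multiplexed capture
#'
#' The multiplexed image shares the camera's 8-bit dynamic range between
#' the incoherent bright-field (LED) and coherent holographic (laser)
#' contributions. Each source has its own gray-level efficiency because
#' the two reach the sensor along very different paths: the default LED
#' gain maps the full 30 mW bright-field background to about 180 gray
#' levels, leaving headroom for the fringes; the laser gain is set so the
#' hologram remains clearly visible on top without saturating at the
#' maximum of the power grid.
#'
#' @param p_laser Laser emission power at the sample plane, mW.
#' @param p_led LED emission power at the sample plane, mW.
#' @param laser_ref_fraction Fraction of the laser power reaching the
#'   sensor that travels in the reference arm. The object arm crosses the
#'   condenser, sample and objective and is strongly attenuated, so the
#'   effective sensor-plane split is heavily reference-dominated;
#'   default 0.95.
#' @param led_gain LED efficiency, gray levels per mW (default 6).
#' @param laser_gain Laser efficiency, gray levels per mW (default 18).
#' @return An object of class `illumination_setting`.
#' @export
illumination_setting <- function(p_laser = 0.4, p_led = 30,
                                 laser_ref_fraction = 0.95,
                                 led_gain = 6, laser_gain = 18) {
  if (p_laser < 0 || p_led < 0) stop("illumination powers must be >= 0")
  if (laser_ref_fraction <= 0 || laser_ref_fraction >= 1)
    stop("laser_ref_fraction must lie in (0, 1)")
  structure(list(p_laser = p_laser, p_led = p_led,
                 laser_ref_fraction = laser_ref_fraction,
                 led_gain = led_gain, laser_gain = laser_gain),
            class = "illumination_setting")
}

#' Sensor and coherence noise model
#'
#' @param shot_noise Poisson photon noise on the expected gray value,
#'   applied at the photoelectron level: `gray = k * Poisson(gray / k)`
#'   with `k = gray_per_electron`, so the background shot noise matches a
#'   realistic CMOS well depth rather than one electron per gray level.
#' @param gray_per_electron Conversion gain `k` (default 0.03; together
#'   with the read noise this puts the full-LED background STD near
#'   2.6 gray levels).
#' @param read_noise_sigma Gaussian read noise, gray levels.
#' @param coherent_artifact_strength RMS amplitude, relative to the unit
#'   background object wave, of parasitic coherent structure added to the
#'   object arm: three fixed-frequency spurious fringe patterns plus
#'   band-limited speckle. This stands in for the coherence-induced
#'   disturbances (dust, internal reflections) that make laser-only
#'   intensity images noisy. Default 0.3.
#' @param seed Integer seed; identical seed and inputs give a
#'   bit-identical image.
#' @return An object of class `noise_model`.
#' @seealso [noise_off()]
#' @export
noise_model <- function(shot_noise = TRUE, gray_per_electron = 0.03,
                        read_noise_sigma = 1.0,
                        coherent_artifact_strength = 0.3,
                        seed = 1L) {
  if (read_noise_sigma < 0) stop("read_noise_sigma must be >= 0")
  if (gray_per_electron <= 0) stop("gray_per_electron must be > 0")
  if (coherent_artifact_strength < 0)
    stop("coherent_artifact_strength must be >= 0")
  structure(list(shot_noise = isTRUE(shot_noise),
                 gray_per_electron = gray_per_electron,
                 read_noise_sigma = read_noise_sigma,
                 coherent_artifact_strength = coherent_artifact_strength,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_off <- function(seed = 1L) {
  noise_model(shot_noise = FALSE, read_noise_sigma = 0,
              coherent_artifact_strength = 0, seed = seed)
}

#' Coherent image of a phantom (object wave at the sensor grid)
#'
#' The object wave is the coherent image of the complex transmittance
#' `a(x, y) * exp(i * phi(x, y))`: the field is low-pass filtered by the
#' circular coherent pupil (radius `NA/(lambda*M)` at the sensor plane).
#' Background amplitude is unity.
#'
#' @param ph A [phantom()].
#' @param config An [optics_config()].
#' @param pupil_cutoff_px Override of the coherent cutoff in cycles/px
#'   (e.g. `Inf` to disable the low-pass for oracle checks).
#' @return Complex matrix of the object wave on the sensor grid.
#' @export
render_object_wave <- function(ph, config, pupil_cutoff_px = NULL) {
  maps <- phantom_maps(ph, config)
  field <- maps$amplitude * exp(1i * maps$phase)
  cut <- if (is.null(pupil_cutoff_px)) pupil_cutoffs_px(config)[["coherent"]]
         else pupil_cutoff_px
  if (!is.finite(cut)) return(field)
  mask <- radial_mask(config$sensor_shape, c(0, 0), cut)
  ifft2(ifftshift(fftshift(fft2(field)) * mask))
}

#' Incoherent bright-field image of a phantom
#'
#' The bright-field intensity is the incoherent image of the intensity
#' transmittance `a^2`, blurred by the incoherent OTF (the normalized
#' autocorrelation of the circular pupil). Phase structure does not
#' contribute: in-focus pure-phase objects are invisible in this model,
#' matching how weakly diffracting cells vanish in focused bright-field.
#'
#' @inheritParams render_object_wave
#' @return Nonnegative intensity matrix (background 1).
#' @export
render_bright_field <- function(ph, config) {
  maps <- phantom_maps(ph, config)
  shape <- config$sensor_shape
  pupil <- radial_mask(shape, c(0, 0), pupil_cutoffs_px(config)[["coherent"]])
  psf <- Mod(ifft2(ifftshift(pupil)))^2
  otf <- fft2(psf)
  otf <- otf / otf[1, 1]
  bfi <- Re(ifft2(fft2(maps$amplitude^2) * otf))
  pmax(bfi, 0)
}

# Parasitic coherent field: three fixed-frequency spurious fringe systems
# plus band-limited speckle, scaled to a total RMS of `strength`.
# Deterministic for a given seed and frame shape.
coherent_artifacts <- function(shape, strength, seed) {
  if (strength <= 0) return(matrix(0 + 0i, shape[1], shape[2]))
  g <- pixel_grids(shape)
  freqs <- list(c(0.021, 0.047), c(-0.069, 0.031), c(0.113, -0.058))
  phases <- c(0.0, 2.1, 4.0)
  fringe_amp <- 0.4 * strength / sqrt(3)
  fr <- matrix(0 + 0i, shape[1], shape[2])
  for (k in seq_along(freqs)) {
    fr <- fr + fringe_amp *
      exp(2i * pi * (freqs[[k]][1] * g$x + freqs[[k]][2] * g$y) + 1i * phases[k])
  }
  speck <- with_seed(seed, function() {
    z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2]) +
      1i * matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    mask <- radial_mask(shape, c(0, 0), 0.15)
    ifft2(ifftshift(fftshift(fft2(z)) * mask))
  })
  speck <- speck / sqrt(mean(Mod(speck)^2)) * sqrt(1 - 0.16) * strength
  fr + speck
}

#' Synthesize a grayscale-multiplexed capture
#'
#' Implements the multiplexed-image forward model: the recorded intensity
#' is proportional to the incoherent bright-field image plus the
#' holographic terms
#' `|O|^2 + |R|^2 + 2 Re(O R*)`, where `R` is a tilted plane-wave
#' reference at the carrier frequency of `config`. The expected gray
#' value is
#' `gain * (led_gain * p_led * BFI +
#'          laser_gain * p_laser * (|O|^2 + |R|^2 + 2 Re(O R*)))`,
#' after which shot/read noise, rounding (half-up) and clipping to the
#' bit depth are applied.
#'
#' @param ph A [phantom()].
#' @param config An [optics_config()].
#' @param illum An [illumination_setting()].
#' @param noise A [noise_model()] (use [noise_off()] for noise-free).
#' @param quantize If `FALSE`, return the continuous expected gray image
#'   before noise and quantization (useful for oracles).
#' @param keep_truth If `TRUE`, attach the ground-truth components
#'   (`bfi`, object wave `O`, expected gray image) in `$truth`.
#' @return An object of class `multiplexed_image` with integer `$pixels`
#'   in `[0, 2^bit_depth - 1]`, plus `$config`, `$illumination`,
#'   `$noise`, `$seed`.
#' @export
synthesize_multiplexed <- function(ph, config, illum = illumination_setting(),
                                   noise = noise_model(), quantize = TRUE,
                                   keep_truth = FALSE) {
  validate_optics(config)
  stopifnot(inherits(illum, "illumination_setting"),
            inherits(noise, "noise_model"))
  shape <- config$sensor_shape
  O <- render_object_wave(ph, config)
  bfi <- render_bright_field(ph, config)
  f <- illum$laser_ref_fraction

  art <- coherent_artifacts(shape, noise$coherent_artifact_strength, noise$seed)
  Oo <- sqrt(1 - f) * (O + art)

  fc <- carrier_frequency_px(config)
  g <- pixel_grids(shape)
  # reference tilted opposite to the carrier axis so that the analytic
  # cross term O*R^ sits at +carrier: objects denser than the medium then
  # demodulate to positive phase
  Rw <- exp(-2i * pi * (fc[1] * g$x + fc[2] * g$y))
  # hologram written with the real-expanded form 2*Re(O R*); identical by
  # algebra to the four-term conjugate sum
  holo <- Mod(Oo)^2 + f + 2 * sqrt(f) * Re(Oo * Conj(Rw))

  expected <- config$gain * (illum$led_gain * illum$p_led * bfi +
                             illum$laser_gain * illum$p_laser * holo)
  full_scale <- 2^config$bit_depth - 1
  if (mean(expected) > full_scale)
    stop("noise-free mean gray value ", signif(mean(expected), 4),
         " exceeds the full scale ", full_scale,
         "; reduce illumination powers or gains")
  if (!quantize) {
    return(structure(list(pixels = expected, config = config,
                          illumination = illum, noise = noise,
                          seed = noise$seed, quantized = FALSE,
                          truth = if (keep_truth)
                            list(bfi = bfi, O = O, expected = expected)),
                     class = "multiplexed_image"))
  }

  gimg <- expected
  if (noise$shot_noise || noise$read_noise_sigma > 0) {
    gimg <- with_seed(noise$seed + 1L, function() {
      out <- expected
      if (noise$shot_noise) {
        k <- noise$gray_per_electron
        out <- k * stats::rpois(length(out), pmax(out, 0) / k)
      }
      if (noise$read_noise_sigma > 0)
        out <- out + stats::rnorm(length(out), 0, noise$read_noise_sigma)
      matrix(out, nrow(expected), ncol(expected))
    })
  }
  px <- pmin(pmax(floor(gimg + 0.5), 0), full_scale)
  n_sat <- sum(px >= full_scale)
  if (n_sat > 0.01 * length(px))
    warning(sprintf("%.1f%% of pixels saturate at full scale",
                    100 * n_sat / length(px)))
  structure(list(pixels = matrix(as.integer(px), shape[1], shape[2]),
                 config = config, illumination = illum, noise = noise,
                 seed = noise$seed, quantized = TRUE,
                 truth = if (keep_truth)
                   list(bfi = bfi, O = O, expected = expected)),
            class = "multiplexed_image")
}

#' @export
print.multiplexed_image <- function(x, ...) {
  cat(sprintf("<multiplexed_image> %d x %d px, p_laser %.2g mW, p_led %.2g mW, seed %d\n",
              nrow(x$pixels), ncol(x$pixels),
              x$illumination$p_laser, x$illumination$p_led, x$seed))
  invisible(x)
}
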