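#' Optical system configuration
#'
#' Bundles all geometry and illumination constants of the multimodal
#' microscope: laser wavelength, camera pixel pitch, magnification,
#' numerical aperture, the small object/reference tilt that creates the
#' off-axis carrier, and the sensor format. All lengths are in metres
#' (SI); angles in degrees.
#'
#' @param wavelength Laser wavelength in metres.
#' @param pixel_pitch Sensor pixel pitch in metres.
#' @param magnification Lateral magnification (> 0).
#' @param numerical_aperture Objective NA, in (0, 1).
#' @param tilt_angle Angle between object and reference waves, degrees.
#' @param tilt_azimuth Orientation of the carrier in the sensor plane,
#'   degrees from the +x (column) axis toward +y (row). The default 45
#'   puts the carrier on the spectral diagonal, maximizing its separation
#'   from the central band on a rectangular sensor.
#' @param sensor_shape Integer `c(rows, cols)` of the sensor.
#' @param bit_depth Camera bit depth (default 8).
#' @param gain Overall sensor conversion, gray levels per unit intensity
#'   (default 1; per-source gray/mW efficiencies live in
#'   [illumination_setting()]).
#'
#' @return An object of class `optics_config`.
#' @seealso [optics_preset()] for the instrument default,
#'   [field_of_view()], [carrier_frequency()], [pupil_cutoffs()].
#' @export
#' @examples
#' cfg <- optics_preset("ts2r-20x")
#' field_of_view(cfg)
optics_config <- function(wavelength, pixel_pitch, magnification,
                          numerical_aperture, tilt_angle,
                          tilt_azimuth = 45,
                          sensor_shape = c(1216L, 1936L),
                          bit_depth = 8L, gain = 1) {
  cfg <- structure(
    list(
      wavelength = wavelength,
      pixel_pitch = pixel_pitch,
      magnification = magnification,
      numerical_aperture = numerical_aperture,
      tilt_angle = tilt_angle,
      tilt_azimuth = tilt_azimuth,
      sensor_shape = as.integer(sensor_shape),
      bit_depth = as.integer(bit_depth),
      gain = gain
    ),
    class = "optics_config"
  )
  validate_optics(cfg)
  cfg
}

#' Validate an optics configuration
#'
#' Checks every invariant and signals an error naming the first violated
#' one: positive lengths and magnification, NA in (0, 1), carrier below
#' the Nyquist frequency, and a fringe period above two pixels so the
#' off-axis fringes are resolvable on the sensor.
#'
#' @param config An `optics_config`.
#' @return `config`, invisibly, if valid.
#' @export
validate_optics <- function(config) {
  stopifnot(inherits(config, "optics_config"))
  if (!is.numeric(config$wavelength) || config$wavelength <= 0)
    stop("invalid optics config: wavelength must be > 0")
  if (!is.numeric(config$pixel_pitch) || config$pixel_pitch <= 0)
    stop("invalid optics config: pixel_pitch must be > 0")
  if (!is.numeric(config$magnification) || config$magnification <= 0)
    stop("invalid optics config: magnification must be > 0")
  na <- config$numerical_aperture
  if (!is.numeric(na) || na <= 0 || na >= 1)
    stop("invalid optics config: numerical_aperture must lie in (0, 1)")
  if (length(config$sensor_shape) != 2L || any(config$sensor_shape < 8L))
    stop("invalid optics config: sensor_shape must be two integers >= 8")
  if (config$tilt_angle < 0 || config$tilt_angle >= 90)
    stop("invalid optics config: tilt_angle must lie in [0, 90) degrees")
  if (config$tilt_angle > 0) {
    f <- sin(config$tilt_angle * pi / 180) / config$wavelength
    nyquist <- 1 / (2 * config$pixel_pitch)
    if (f >= nyquist)
      stop("invalid optics config: carrier frequency ", signif(f, 4),
           " cycles/m is not below the Nyquist frequency ",
           signif(nyquist, 4),
           " cycles/m (fringe period must exceed 2 px)")
  }
  invisible(config)
}

#' Instrument presets
#'
#' `"ts2r-20x"` is the multimodal instrument default: 532 nm laser,
#' 5.86 um pixel pitch, 20x / NA 0.40 objective, 1.9 degree off-axis
#' tilt, 1936 x 1216 px monochrome sensor, 8 bit.
#'
#' @param name Preset name; only `"ts2r-20x"` is defined.
#' @param sensor_shape Optional `c(rows, cols)` override, e.g.
#'   `c(512, 512)` for desk-scale simulation frames.
#' @return An [optics_config()].
#' @export
optics_preset <- function(name = "ts2r-20x", sensor_shape = NULL) {
  name <- match.arg(name)
  cfg <- optics_config(
    wavelength = 532e-9,
    pixel_pitch = 5.86e-6,
    magnification = 20,
    numerical_aperture = 0.40,
    tilt_angle = 1.9,
    tilt_azimuth = 45,
    sensor_shape = c(1216L, 1936L),
    bit_depth = 8L,
    gain = 1
  )
  if (!is.null(sensor_shape)) {
    cfg$sensor_shape <- as.integer(sensor_shape)
    validate_optics(cfg)
  }
  cfg
}

#' Field of view at the object plane
#'
#' @param config An `optics_config`.
#' @return Named numeric `c(width, height)` in micrometres:
#'   `cols * pixel_pitch / M` by `rows * pixel_pitch / M`.
#' @export
#' @examples
#' round(field_of_view(optics_preset())) # 567 x 356 um
field_of_view <- function(config) {
  validate_optics(config)
  c(width = config$sensor_shape[2] * config$pixel_pitch / config$magnification,
    height = config$sensor_shape[1] * config$pixel_pitch / config$magnification) * 1e6
}

#' Off-axis carrier frequency
#'
#' The spatial frequency of the interference fringes produced by the
#' object/reference tilt: magnitude `sin(tilt)/wavelength`, direction set
#' by the tilt azimuth.
#'
#' @param config An `optics_config`.
#' @return `carrier_frequency()`: named `c(fx, fy)` in cycles/m at the
#'   sensor plane. `carrier_frequency_px()`: the same in cycles/pixel.
#' @export
carrier_frequency <- function(config) {
  validate_optics(config)
  f <- sin(config$tilt_angle * pi / 180) / config$wavelength
  az <- config$tilt_azimuth * pi / 180
  c(fx = f * cos(az), fy = f * sin(az))
}

#' @rdname carrier_frequency
#' @export
carrier_frequency_px <- function(config) {
  carrier_frequency(config) * config$pixel_pitch
}

#' Tilt angle implied by a carrier frequency
#'
#' Inverse of [carrier_frequency()]: `asin(|f| * wavelength)` where `f`
#' is given in cycles/m, or `asin(|f_px| * wavelength / pixel_pitch)` for
#' cycles/pixel.
#'
#' @param f Carrier frequency vector or magnitude.
#' @param config An `optics_config` (supplies wavelength and pitch).
#' @param units `"cycles_per_m"` or `"cycles_per_px"`.
#' @return Angle in degrees.
#' @export
carrier_angle <- function(f, config, units = c("cycles_per_m", "cycles_per_px")) {
  units <- match.arg(units)
  mag <- sqrt(sum(f^2))
  s <- if (units == "cycles_per_m") mag * config$wavelength
       else mag * config$wavelength / config$pixel_pitch
  if (s > 1) stop("carrier frequency exceeds the propagating range")
  asin(s) * 180 / pi
}

#' Fringe period of the off-axis carrier, in sensor pixels
#'
#' @param config An `optics_config`.
#' @return `wavelength / (sin(tilt) * pixel_pitch)` (Inf for zero tilt).
#' @export
fringe_period_px <- function(config) {
  validate_optics(config)
  s <- sin(config$tilt_angle * pi / 180)
  if (s == 0) return(Inf)
  config$wavelength / (s * config$pixel_pitch)
}

#' Pupil cutoff frequencies at the sensor plane
#'
#' Standard imaging theory: the coherent transfer function is a disk of
#' radius `NA/(wavelength * M)` (frequencies referred to the sensor
#' plane); the incoherent OTF support is its autocorrelation, twice that
#' radius.
#'
#' @param config An `optics_config`.
#' @return `pupil_cutoffs()`: named `c(coherent, incoherent)` in
#'   cycles/m; `pupil_cutoffs_px()` the same in cycles/pixel.
#' @export
pupil_cutoffs <- function(config) {
  validate_optics(config)
  coh <- config$numerical_aperture / (config$wavelength * config$magnification)
  c(coherent = coh, incoherent = 2 * coh)
}

#' @rdname pupil_cutoffs
#' @export
pupil_cutoffs_px <- function(config) {
  pupil_cutoffs(config) * config$pixel_pitch
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  wavelength         %.1f nm\n", x$wavelength * 1e9))
  cat(sprintf("  pixel pitch        %.2f um\n", x$pixel_pitch * 1e6))
  cat(sprintf("  magnification      %gx   NA %.2f\n",
              x$magnification, x$numerical_aperture))
  cat(sprintf("  tilt               %.2f deg @ azimuth %.0f deg\n",
              x$tilt_angle, x$tilt_azimuth))
  cat(sprintf("  sensor             %d x %d px, %d bit\n",
              x$sensor_shape[1], x$sensor_shape[2], x$bit_depth))
  fov <- field_of_view(x)
  cat(sprintf("  FOV                %.1f x %.1f um\n", fov[1], fov[2]))
  if (x$tilt_angle > 0)
    cat(sprintf("  fringe period      %.2f px\n", fringe_period_px(x)))
  invisible(x)
}

#' Read / write an optics configuration file
#'
#' Flat key:value text files (YAML dialect) mirroring the
#' [optics_config()] fields, with explicit unit suffixes in the key
#' names (`wavelength_nm`, `pixel_pitch_um`, `tilt_angle_deg`, ...).
#' Invariants are validated on read.
#'
#' @param path File path.
#' @param config An `optics_config` (for writing).
#' @return `read_optics_config()` returns an `optics_config`.
#' @export
read_optics_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("wavelength_nm", "pixel_pitch_um", "magnification",
            "numerical_aperture", "tilt_angle_deg")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("optics config file is missing keys: ", paste(missing, collapse = ", "))
  optics_config(
    wavelength = y$wavelength_nm * 1e-9,
    pixel_pitch = y$pixel_pitch_um * 1e-6,
    magnification = y$magnification,
    numerical_aperture = y$numerical_aperture,
    tilt_angle = y$tilt_angle_deg,
    tilt_azimuth = if (!is.null(y$tilt_azimuth_deg)) y$tilt_azimuth_deg else 45,
    sensor_shape = c(
      if (!is.null(y$sensor_rows)) y$sensor_rows else 1216L,
      if (!is.null(y$sensor_cols)) y$sensor_cols else 1936L
    ),
    bit_depth = if (!is.null(y$bit_depth)) y$bit_depth else 8L,
    gain = if (!is.null(y$gain)) y$gain else 1
  )
}

#' @rdname read_optics_config
#' @export
write_optics_config <- function(config, path) {
  validate_optics(config)
  yaml::write_yaml(list(
    wavelength_nm = config$wavelength * 1e9,
    pixel_pitch_um = config$pixel_pitch * 1e6,
    magnification = config$magnification,
    numerical_aperture = config$numerical_aperture,
    tilt_angle_deg = config$tilt_angle,
    tilt_azimuth_deg = config$tilt_azimuth,
    sensor_rows = config$sensor_shape[1],
    sensor_cols = config$sensor_shape[2],
    bit_depth = config$bit_depth,
    gain = config$gain
  ), path)
  invisible(path)
}
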