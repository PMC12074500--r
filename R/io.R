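#' Read a multiplexed capture from disk
#'
#' Accepts single-channel 8- or 16-bit TIFF or PNG files. Multi-channel
#' input is rejected. A sidecar metadata file (`<path>.yaml`, written by
#' [write_capture()]) restores the illumination settings and seed; the
#' optics configuration can come from the sidecar, from `config`, or
#' from a config file.
#'
#' @param path Image file (.tif/.tiff/.png).
#' @param config Optional [optics_config()] to attach; overrides any
#'   sidecar geometry.
#' @return A `multiplexed_image`.
#' @export
read_capture <- function(path, config = NULL) {
  if (!file.exists(path)) stop("cannot read capture: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    bits <- attr(px, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    px <- round(px * (2^bits - 1))
  } else {
    stop("unsupported capture format '.", ext, "': use TIFF or PNG")
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1L)
      stop("multi-channel input rejected: captures must be single-channel grayscale")
    px <- px[, , 1]
  }
  if (length(bits) && !all(bits %in% c(8L, 16L)))
    stop("unsupported bit depth ", bits[1], ": captures must be 8- or 16-bit")
  sidecar <- paste0(path, ".yaml")
  illum <- illumination_setting()
  noise <- noise_model()
  seed <- NA_integer_
  if (file.exists(sidecar)) {
    y <- yaml::read_yaml(sidecar)
    if (!is.null(y$p_laser_mw))
      illum <- illumination_setting(
        p_laser = y$p_laser_mw, p_led = y$p_led_mw,
        laser_ref_fraction = y$laser_ref_fraction %||% 0.95,
        led_gain = y$led_gain %||% 6, laser_gain = y$laser_gain %||% 18)
    if (!is.null(y$seed)) seed <- as.integer(y$seed)
    if (is.null(config) && !is.null(y$optics))
      config <- do.call(optics_config, y$optics)
  }
  if (is.null(config))
    config <- optics_preset("ts2r-20x", sensor_shape = dim(px))
  if (!all(dim(px) == config$sensor_shape))
    stop("capture shape ", paste(dim(px), collapse = " x "),
         " does not match config sensor_shape ",
         paste(config$sensor_shape, collapse = " x "))
  if (max(px) > 2^config$bit_depth - 1)
    stop("pixel values exceed the declared bit depth ",
         config$bit_depth, " of the attached config")
  structure(list(pixels = matrix(as.integer(px), nrow(px), ncol(px)),
                 config = config, illumination = illum, noise = noise,
                 seed = seed, quantized = TRUE, truth = NULL),
            class = "multiplexed_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multiplexed capture and its sidecar metadata
#'
#' 8-bit grayscale TIFF or PNG (by extension), plus `<path>.yaml`
#' recording the illumination powers, seed and a digest of the optics
#' configuration — enough provenance to reproduce the capture.
#'
#' @param image A `multiplexed_image`.
#' @param path Output file (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_capture <- function(image, path) {
  stopifnot(inherits(image, "multiplexed_image"))
  full <- 2^image$config$bit_depth - 1
  norm <- image$pixels / full
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  else if (ext == "png")
    png::writePNG(norm, path)
  else stop("unsupported capture format '.", ext, "'")
  cfg <- image$config
  yaml::write_yaml(list(
    p_laser_mw = image$illumination$p_laser,
    p_led_mw = image$illumination$p_led,
    laser_ref_fraction = image$illumination$laser_ref_fraction,
    led_gain = image$illumination$led_gain,
    laser_gain = image$illumination$laser_gain,
    seed = if (is.na(image$seed)) NULL else image$seed,
    config_hash = config_hash(cfg),
    optics = list(
      wavelength = cfg$wavelength, pixel_pitch = cfg$pixel_pitch,
      magnification = cfg$magnification,
      numerical_aperture = cfg$numerical_aperture,
      tilt_angle = cfg$tilt_angle, tilt_azimuth = cfg$tilt_azimuth,
      sensor_shape = cfg$sensor_shape, bit_depth = cfg$bit_depth,
      gain = cfg$gain
    )
  ), paste0(path, ".yaml"))
  invisible(path)
}

config_hash <- function(config) {
  s <- paste(unlist(config[c("wavelength", "pixel_pitch", "magnification",
                             "numerical_aperture", "tilt_angle",
                             "tilt_azimuth", "sensor_shape", "bit_depth",
                             "gain")]), collapse = "|")
  # small stable polynomial hash; provenance only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a floating-point map as 32-bit TIFF
#'
#' Phase maps (radians) and thickness maps (micrometres) are stored as
#' 32-bit float TIFF normalized to \[0, 1\], with the affine mapping
#' (offset, scale) recorded in a `<path>.yaml` sidecar so the physical
#' values are recovered exactly on read.
#'
#' @param map Numeric matrix.
#' @param path Output .tif path.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(map, path) {
  offset <- min(map)
  scale <- max(map) - offset
  if (scale == 0) scale <- 1
  tiff::writeTIFF((map - offset) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(offset = offset, scale = scale, units = "map"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a 32-bit float TIFF map
#'
#' Applies the affine mapping from the `<path>.yaml` sidecar when
#' present.
#'
#' @param path Input .tif path.
#' @return Numeric matrix.
#' @export
read_phase_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    y <- yaml::read_yaml(sidecar)
    m <- m * y$scale + y$offset
  }
  m
}

# Run manifest: every pipeline output references the parameters actually
# used, so a run can be reproduced bit-identically.
write_manifest <- function(path, inputs, params, outputs) {
  jsonlite::write_json(list(
    tool = "bfdhm",
    version = as.character(utils::packageVersion("bfdhm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs, parameters = params, outputs = outputs
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
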