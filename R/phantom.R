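#' Ground-truth phantom scenes
#'
#' A phantom describes the object plane: a surrounding medium refractive
#' index, a set of spherical inclusions (microspheres) with their own
#' refractive indices and optional transmittance, and an optional
#' absorption (transmittance) map. The phantom grid always matches the
#' demagnified sensor grid exactly (no resampling), so simulated
#' fixtures are bit-reproducible.
#'
#' @param medium_ri Refractive index of the immersion medium (>= 1).
#'   Default 1.43, a 70/30 glycerin-water solution.
#' @param absorption_map Optional matrix of transmittance values in
#'   \[0, 1\] on the object-plane grid (default 1 everywhere).
#' @return An object of class `phantom`.
#' @seealso [add_sphere()], [phantom_maps()]
#' @export
#' @examples
#' ph <- add_sphere(phantom(), x = 75, y = 75, radius = 5, ri = 1.48)
phantom <- function(medium_ri = 1.43, absorption_map = NULL) {
  if (medium_ri < 1) stop("medium_ri must be >= 1")
  if (!is.null(absorption_map) &&
      (any(absorption_map < 0) || any(absorption_map > 1)))
    stop("absorption_map transmittance must lie in [0, 1]")
  structure(
    list(
      medium_ri = medium_ri,
      spheres = data.frame(x = numeric(), y = numeric(),
                           radius = numeric(), ri = numeric(),
                           transmittance = numeric()),
      absorption_map = absorption_map
    ),
    class = "phantom"
  )
}

#' Add a sphere to a phantom
#'
#' @param ph A [phantom()].
#' @param x,y Centre in object-plane micrometres (origin at the top-left
#'   pixel centre).
#' @param radius Sphere radius in micrometres.
#' @param ri Sphere refractive index (>= 1). Default 1.48 (PMMA).
#' @param transmittance Intensity transmittance of the projected disk in
#'   \[0, 1\] (1 = pure phase object).
#' @return The phantom with the sphere appended.
#' @export
add_sphere <- function(ph, x, y, radius, ri = 1.48, transmittance = 1) {
  stopifnot(inherits(ph, "phantom"))
  if (ri < 1) stop("sphere refractive index must be >= 1")
  if (radius <= 0) stop("sphere radius must be > 0")
  if (transmittance < 0 || transmittance > 1)
    stop("transmittance must lie in [0, 1]")
  ph$spheres <- rbind(ph$spheres,
                      data.frame(x = x, y = y, radius = radius, ri = ri,
                                 transmittance = transmittance))
  ph
}

#' Chord thickness of a sphere
#'
#' Projected thickness profile `t(rho) = 2 * sqrt(r^2 - rho^2)` for
#' `rho <= r`, else 0.
#'
#' @param rho Radial distance(s) from the sphere centre (um).
#' @param radius Sphere radius (um).
#' @return Thickness in the same units as `radius`.
#' @export
sphere_thickness <- function(rho, radius) {
  t <- 2 * sqrt(pmax(radius^2 - rho^2, 0))
  t[rho > radius] <- 0
  t
}

# Object-plane pixel coordinates (um) for a config: pixel j has
# x = (j-1) * pixel_pitch / M.
object_plane_axes <- function(config) {
  pitch <- config$pixel_pitch / config$magnification * 1e6
  list(
    x = (seq_len(config$sensor_shape[2]) - 1) * pitch,
    y = (seq_len(config$sensor_shape[1]) - 1) * pitch,
    pitch = pitch
  )
}

#' Rasterize a phantom onto the sensor-conjugate grid
#'
#' Renders the ground-truth maps used by the simulator: the physical
#' thickness map of all spheres, the optical phase delay
#' `phi = 2 * pi * (n_sphere - n_medium) * t / lambda`, and the amplitude
#' transmittance `a = sqrt(transmittance)`.
#'
#' @param ph A [phantom()].
#' @param config An [optics_config()]; the phantom grid is the
#'   demagnified sensor grid.
#' @return List with matrices `thickness` (um), `phase` (rad),
#'   `amplitude`, plus the object-plane `pitch` (um/px).
#' @export
phantom_maps <- function(ph, config) {
  stopifnot(inherits(ph, "phantom"))
  validate_optics(config)
  shape <- config$sensor_shape
  ax <- object_plane_axes(config)
  thickness <- matrix(0, shape[1], shape[2])
  phase <- matrix(0, shape[1], shape[2])
  trans <- matrix(1, shape[1], shape[2])
  lambda_um <- config$wavelength * 1e6
  if (nrow(ph$spheres)) {
    X <- matrix(ax$x, shape[1], shape[2], byrow = TRUE)
    Y <- matrix(ax$y, shape[1], shape[2])
    for (k in seq_len(nrow(ph$spheres))) {
      s <- ph$spheres[k, ]
      rho <- sqrt((X - s$x)^2 + (Y - s$y)^2)
      t_k <- sphere_thickness(rho, s$radius)
      thickness <- thickness + t_k
      phase <- phase + 2 * pi * (s$ri - ph$medium_ri) * t_k / lambda_um
      if (s$transmittance < 1) {
        inside <- rho <= s$radius
        trans[inside] <- trans[inside] * s$transmittance
      }
    }
  }
  if (!is.null(ph$absorption_map)) {
    if (!all(dim(ph$absorption_map) == shape))
      stop("absorption_map shape does not match the sensor grid (",
           paste(shape, collapse = " x "), ")")
    trans <- trans * ph$absorption_map
  }
  list(thickness = thickness, phase = phase, amplitude = sqrt(trans),
       pitch = ax$pitch)
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> medium RI", x$medium_ri, "with", nrow(x$spheres),
      "sphere(s)\n")
  if (nrow(x$spheres)) print(x$spheres)
  invisible(x)
}
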