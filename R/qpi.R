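#' Two-dimensional phase unwrapping
#'
#' Reliability-sorting region-growing unwrapper: pixels are merged along
#' edges in decreasing order of a second-difference reliability measure,
#' each merge shifting a whole region by an integer multiple of 2*pi.
#' The algorithm is total and deterministic; the output is pixelwise
#' congruent to the input modulo 2*pi. The number of phase residues in
#' the wrapped input is attached as a diagnostic.
#'
#' @param wrapped Matrix of wrapped phases in (-pi, pi].
#' @return Unwrapped phase matrix with attribute `residues`.
#' @export
#' @examples
#' ramp <- matrix(seq(0, 4 * pi, length.out = 64), 64, 64, byrow = TRUE)
#' w <- Arg(exp(1i * ramp))
#' u <- unwrap_phase(w)
#' max(abs((u - u[1, 1]) - (ramp - ramp[1, 1]))) < 1e-9
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped))
  if (any(wrapped > pi + 1e-9) || any(wrapped <= -pi - 1e-9))
    stop("wrapped phase must lie in (-pi, pi]")
  res <- unwrap_phase_cpp(wrapped)
  out <- res$unwrapped
  attr(out, "residues") <- res$residues
  out
}

# 2D polynomial design matrix, total degree <= degree, over coordinates
# normalized to [-1, 1] (keeps the fit well conditioned).
poly_design <- function(shape, degree) {
  xs <- if (shape[2] > 1) seq(-1, 1, length.out = shape[2]) else 0
  ys <- if (shape[1] > 1) seq(-1, 1, length.out = shape[1]) else 0
  X <- matrix(xs, shape[1], shape[2], byrow = TRUE)
  Y <- matrix(ys, shape[1], shape[2])
  cols <- list()
  for (d in 0:degree)
    for (px in 0:d)
      cols[[length(cols) + 1L]] <- as.vector(X^px * Y^(d - px))
  do.call(cbind, cols)
}

#' Default corner background mask
#'
#' Logical mask marking four corner rectangles, each `frac` of the rows
#' by `frac` of the columns, conventionally sample-free in the
#' characterization scenes. The default 12% per side covers 5.76% of the
#' frame, enough support for the degree-4 aberration fit.
#'
#' @param shape `c(rows, cols)`.
#' @param frac Side fraction of each corner rectangle (default 0.12).
#' @param margin Inset from the frame border in pixels (default 8):
#'   FFT-based demodulation rings at the periodic frame boundary, so
#'   background statistics are taken slightly inside it.
#' @return Logical matrix.
#' @export
corner_mask <- function(shape, frac = 0.12, margin = 8L) {
  nr <- max(2L, round(frac * shape[1]))
  nc <- max(2L, round(frac * shape[2]))
  m <- matrix(FALSE, shape[1], shape[2])
  rows <- c(margin + seq_len(nr), shape[1] - margin - seq_len(nr) + 1L)
  cols <- c(margin + seq_len(nc), shape[2] - margin - seq_len(nc) + 1L)
  m[rows, cols] <- TRUE
  m
}

#' Compensate smooth phase aberrations
#'
#' Removes the residual carrier tilt and the setup-specific smooth
#' (spherical-type) phase aberration by least-squares fitting a 2D
#' polynomial of total degree `poly_degree` to the unwrapped phase
#' restricted to a sample-free background mask, then subtracting the
#' fitted surface everywhere. Degree 4 covers tilt plus the r^2 and r^4
#' spherical terms. Requires no knowledge of the specimen, only of
#' sample-free regions.
#'
#' @param x Unwrapped phase matrix, or a complex image (its argument is
#'   unwrapped first).
#' @param background_mask Logical matrix of sample-free pixels; default
#'   [corner_mask()]. Must cover at least 5% of the frame.
#' @param poly_degree Total polynomial degree (default 4).
#' @return Compensated phase matrix (background fit subtracted).
#' @export
compensate_aberrations <- function(x, background_mask = NULL,
                                   poly_degree = 4) {
  if (is.complex(x)) x <- unwrap_phase(Arg(x))
  stopifnot(is.matrix(x))
  shape <- dim(x)
  if (is.null(background_mask)) background_mask <- corner_mask(shape)
  if (!is.logical(background_mask) || !all(dim(background_mask) == shape))
    stop("background_mask must be a logical matrix matching the phase map")
  if (mean(background_mask) < 0.05)
    stop("background mask covers ", signif(100 * mean(background_mask), 3),
         "% of pixels; at least 5% is required for a stable fit")
  D <- poly_design(shape, poly_degree)
  sel <- as.vector(background_mask)
  fit <- stats::lm.fit(D[sel, , drop = FALSE], as.vector(x)[sel])
  if (fit$rank < ncol(D))
    stop("aberration fit is rank deficient (mask too small or degenerate)")
  x - matrix(D %*% fit$coefficients, shape[1], shape[2])
}

#' Background rectangles for noise and offset estimation
#'
#' Axis-aligned rectangles declared sample-free, used both for
#' background-STD noise metrics and for background plane subtraction.
#'
#' @param rects Matrix or data.frame with columns `row, col, height,
#'   width` (1-based top-left corner).
#' @param shape Frame shape `c(rows, cols)` for validation.
#' @return An object of class `background_rois`.
#' @seealso [corner_rois()], [roi_mask()]
#' @export
background_rois <- function(rects, shape = NULL) {
  rects <- as.data.frame(rects)
  names(rects) <- c("row", "col", "height", "width")[seq_len(ncol(rects))]
  if (!nrow(rects)) stop("at least one background ROI is required")
  if (!is.null(shape)) {
    if (any(rects$row < 1 | rects$col < 1 |
            rects$row + rects$height - 1 > shape[1] |
            rects$col + rects$width - 1 > shape[2]))
      stop("background ROI extends outside the frame")
    if (sum(rects$height * rects$width) < 0.01 * prod(shape))
      stop("background ROIs must cover at least 1% of the frame")
  }
  structure(list(rects = rects, shape = shape), class = "background_rois")
}

#' @rdname background_rois
#' @param frac Side fraction of each corner rectangle.
#' @param margin Inset from the frame border in pixels (see
#'   [corner_mask()]).
#' @export
corner_rois <- function(shape, frac = 0.12, margin = 8L) {
  nr <- max(2L, round(frac * shape[1]))
  nc <- max(2L, round(frac * shape[2]))
  background_rois(data.frame(
    row = c(1L, 1L, shape[1] - nr + 1L, shape[1] - nr + 1L) +
      c(margin, margin, -margin, -margin),
    col = c(1L, shape[2] - nc + 1L, 1L, shape[2] - nc + 1L) +
      c(margin, -margin, margin, -margin),
    height = nr, width = nc
  ), shape)
}

#' @rdname background_rois
#' @param rois A `background_rois`.
#' @export
roi_mask <- function(rois, shape) {
  stopifnot(inherits(rois, "background_rois"))
  m <- matrix(FALSE, shape[1], shape[2])
  for (k in seq_len(nrow(rois$rects))) {
    r <- rois$rects[k, ]
    m[r$row:(r$row + r$height - 1), r$col:(r$col + r$width - 1)] <- TRUE
  }
  m
}

#' Subtract the background phase plane
#'
#' Fits a plane by least squares over the pixels of the declared
#' sample-free ROIs, subtracts it everywhere, and removes the remaining
#' ROI median so the background sits at zero.
#'
#' @param phase Phase matrix (rad).
#' @param rois A [background_rois()]; default [corner_rois()].
#' @return Background-flattened phase map.
#' @export
subtract_background <- function(phase, rois = NULL) {
  stopifnot(is.matrix(phase))
  shape <- dim(phase)
  if (is.null(rois)) rois <- corner_rois(shape)
  mask <- roi_mask(rois, shape)
  if (!any(mask)) stop("background ROI set selects no pixels")
  D <- poly_design(shape, 1)
  sel <- as.vector(mask)
  fit <- stats::lm.fit(D[sel, , drop = FALSE], as.vector(phase)[sel])
  out <- phase - matrix(D %*% fit$coefficients, shape[1], shape[2])
  out - stats::median(out[mask])
}

#' Convert phase to physical thickness
#'
#' `t = phi * lambda / (2 * pi * delta_n)`: the optical path delay
#' divided by the refractive-index difference between object and medium.
#'
#' @param phase Phase (rad), scalar or matrix.
#' @param wavelength Wavelength in metres.
#' @param delta_n Refractive-index difference (must be nonzero).
#' @return Thickness in micrometres, same shape as `phase`.
#' @export
#' @examples
#' phase_to_thickness(5.905, 532e-9, 0.05) # ~10 um
phase_to_thickness <- function(phase, wavelength, delta_n) {
  if (delta_n == 0) stop("delta_n must be nonzero")
  phase * wavelength / (2 * pi * delta_n) * 1e6
}

#' Full quantitative-phase reconstruction of a multiplexed capture
#'
#' Runs the QPI branch of the demultiplexing pipeline: spectrum, carrier
#' location, cross-band extraction and demodulation, phase unwrapping,
#' polynomial aberration compensation, background plane subtraction, and
#' (optionally) thickness conversion.
#'
#' @param image A `multiplexed_image` (or matrix plus `config`).
#' @param config Optics configuration; taken from the image if omitted.
#' @param delta_n Optional refractive-index difference for the thickness
#'   map.
#' @param cross_radius,soft_edge Cross-band mask geometry (cycles/px);
#'   defaults as in [extract_cross_band()].
#' @param background_mask Mask for [compensate_aberrations()].
#' @param rois ROIs for [subtract_background()].
#' @param poly_degree Aberration fit degree (default 4).
#' @param window Hann window in [compute_spectrum()].
#' @return An object of class `qpi_result`: `$wrapped`, `$unwrapped`,
#'   `$phase` (compensated), `$qpi` (background-subtracted), optional
#'   `$thickness` (um), `$carrier`, `$cross_radius`, `$residues`.
#' @export
reconstruct_qpi <- function(image, config = NULL, delta_n = NULL,
                            cross_radius = NULL, soft_edge = NULL,
                            background_mask = NULL, rois = NULL,
                            poly_degree = 4, window = FALSE) {
  if (inherits(image, "multiplexed_image") && is.null(config))
    config <- image$config
  if (is.null(config)) stop("an optics config is required")
  sp <- compute_spectrum(image, window = window)
  sp$config <- config
  car <- locate_carrier(sp)
  user_radius <- !is.null(cross_radius)
  if (!user_radius)
    cross_radius <- min(pupil_cutoffs_px(config)[["coherent"]],
                        0.5 * sqrt(sum(car$f_px^2)))
  car$f_px <- refine_carrier(sp, car$f_px, cross_radius)
  car$angle_deg <- carrier_angle(car$f_px, config, "cycles_per_px")
  if (!user_radius)
    cross_radius <- min(pupil_cutoffs_px(config)[["coherent"]],
                        0.5 * sqrt(sum(car$f_px^2)))
  Bc <- extract_cross_band(sp, car$f_px, cross_radius, soft_edge)
  wrapped <- Arg(Bc)
  unwrapped <- unwrap_phase(wrapped)
  comp <- compensate_aberrations(unwrapped, background_mask, poly_degree)
  qpi <- subtract_background(comp, rois)
  structure(list(
    wrapped = wrapped, unwrapped = unwrapped, phase = comp, qpi = qpi,
    thickness = if (!is.null(delta_n))
      phase_to_thickness(qpi, config$wavelength, delta_n),
    carrier = car, cross_radius = cross_radius,
    residues = attr(unwrapped, "residues")
  ), class = "qpi_result")
}

#' @export
print.qpi_result <- function(x, ...) {
  cat(sprintf("<qpi_result> %d x %d px, carrier (%.4f, %.4f) cyc/px",
              nrow(x$qpi), ncol(x$qpi), x$carrier$f_px[1], x$carrier$f_px[2]))
  if (!is.null(x$carrier$angle_deg))
    cat(sprintf(" (tilt %.2f deg)", x$carrier$angle_deg))
  cat(sprintf("\n  phase range [%.2f, %.2f] rad, %d residues\n",
              min(x$qpi), max(x$qpi), x$residues))
  invisible(x)
}
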