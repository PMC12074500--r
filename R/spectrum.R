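#' Fourier spectrum of a multiplexed capture
#'
#' 2D FFT of the image, returned DC-centered. In the spectrum the
#' holographic cross-correlation terms sit at plus/minus the carrier
#' frequency while the bright-field and holographic autocorrelation
#' energy is centred on DC, which is what makes single-capture
#' demultiplexing possible.
#'
#' @param image A `multiplexed_image` or a numeric matrix.
#' @param window Apply a Hann window before the FFT (reduces leakage at
#'   the cost of Parseval exactness). Default off.
#' @param subtract_mean Remove the mean before the FFT. Default off (the
#'   DC level carries the bright-field background).
#' @return An object of class `dhm_spectrum`: `$S` (DC-centered complex
#'   matrix), `$shape`, and the source `$config` when available.
#' @export
compute_spectrum <- function(image, window = FALSE, subtract_mean = FALSE) {
  config <- NULL
  if (inherits(image, "multiplexed_image")) {
    config <- image$config
    image <- image$pixels
  }
  m <- image * 1.0
  if (subtract_mean) m <- m - mean(m)
  if (window) m <- m * hann2(dim(m))
  structure(list(S = fftshift(fft2(m)), shape = dim(m), config = config,
                 window = window, subtract_mean = subtract_mean),
            class = "dhm_spectrum")
}

as_spectrum <- function(x, ...) {
  if (inherits(x, "dhm_spectrum")) x
  else compute_spectrum(x, ...)
}

#' Locate the off-axis carrier peak
#'
#' Finds the cross-correlation peak of the spectrum: the argmax of the
#' magnitude outside a DC exclusion disk, restricted to the half-plane
#' with positive fx (tie-break), refined to subpixel precision by a 3x3
#' quadratic fit on the log-magnitude. A carrier is accepted only when
#' the peak stands at least `min_ratio` times above the local spectral
#' floor (median magnitude in a surrounding annulus); otherwise a
#' "no carrier detected" error signals that the hologram contrast is too
#' low (e.g. the laser was off).
#'
#' @param spectrum A `dhm_spectrum` (or anything [compute_spectrum()]
#'   accepts).
#' @param exclusion_radius DC exclusion radius in cycles/px. Default:
#'   1.5x the coherent pupil cutoff when a config is attached, else 0.15.
#' @param min_ratio Minimum peak-to-floor ratio (default 3).
#' @return List with `f_px` (named `c(fx, fy)`, cycles/px), `magnitude`,
#'   `ratio`, and `angle_deg` (when a config is attached).
#' @export
locate_carrier <- function(spectrum, exclusion_radius = NULL, min_ratio = 3) {
  sp <- as_spectrum(spectrum)
  if (is.null(exclusion_radius)) {
    exclusion_radius <- if (!is.null(sp$config))
      1.5 * pupil_cutoffs_px(sp$config)[["coherent"]] else 0.15
  }
  mag <- Mod(sp$S)
  g <- freq_grids(sp$shape)
  rho <- sqrt(g$fx^2 + g$fy^2)
  search <- mag
  search[rho <= exclusion_radius] <- -Inf
  # half-plane tie-break: keep fx > 0, or the fx == 0 column with fy > 0
  search[g$fx < 0] <- -Inf
  search[g$fx == 0 & g$fy <= 0] <- -Inf
  idx <- which.max(search)
  i0 <- (idx - 1L) %% sp$shape[1] + 1L
  j0 <- (idx - 1L) %/% sp$shape[1] + 1L
  peak <- mag[i0, j0]

  # spectral floor: high quantile of the search region. A genuine carrier
  # is a near-delta peak standing far above it, while the maximum of a
  # peakless (noise or bright-field-only) spectrum sits close to its own
  # upper quantiles.
  candidates <- search[is.finite(search)]
  floor_level <- stats::quantile(candidates, 0.999, names = FALSE)
  ratio <- if (floor_level <= 0) Inf else peak / floor_level
  if (!is.finite(peak) || ratio < min_ratio)
    stop("no carrier detected: spectral peak-to-floor ratio ",
         signif(ratio, 3), " is below ", min_ratio,
         " (hologram contrast too low or laser off)")

  # subpixel refinement by separable quadratic fit on log-magnitude
  refine <- function(lm1, lc, lp1) {
    den <- lm1 - 2 * lc + lp1
    if (!is.finite(den) || den >= 0) return(0)
    max(min(0.5 * (lm1 - lp1) / den, 0.5), -0.5)
  }
  eps <- max(mag) * 1e-12
  lg <- function(i, j) log(mag[i, j] + eps)
  dr <- if (i0 > 1 && i0 < sp$shape[1])
    refine(lg(i0 - 1, j0), lg(i0, j0), lg(i0 + 1, j0)) else 0
  dc <- if (j0 > 1 && j0 < sp$shape[2])
    refine(lg(i0, j0 - 1), lg(i0, j0), lg(i0, j0 + 1)) else 0

  fy <- (i0 - 1 - floor(sp$shape[1] / 2) + dr) / sp$shape[1]
  fx <- (j0 - 1 - floor(sp$shape[2] / 2) + dc) / sp$shape[2]
  out <- list(f_px = c(fx = fx, fy = fy), magnitude = peak, ratio = ratio)
  if (!is.null(sp$config))
    out$angle_deg <- carrier_angle(out$f_px, sp$config, "cycles_per_px")
  out
}

#' Refine a carrier estimate from the demodulated phase gradient
#'
#' One quadratic-fit peak estimate is only accurate to a small fraction
#' of a spectral bin, which still leaves a visible residual tilt across
#' the demodulated phase. This refinement demodulates at the current
#' estimate and measures the remaining carrier as the median wrapped
#' phase increment along rows and columns (robust to objects in the
#' scene), then updates the estimate. Two iterations reduce the residual
#' ramp to the numerical floor.
#'
#' @param spectrum A `dhm_spectrum`.
#' @param f0 Initial carrier estimate `c(fx, fy)` in cycles/px.
#' @param radius Demodulation mask radius (cycles/px).
#' @param iterations Number of refinement passes (default 2).
#' @return Refined `c(fx, fy)`.
#' @export
refine_carrier <- function(spectrum, f0, radius, iterations = 2) {
  sp <- as_spectrum(spectrum)
  border <- max(4L, ceiling(0.03 * min(sp$shape)))
  ri <- (border + 1):(sp$shape[1] - border)
  ci <- (border + 1):(sp$shape[2] - border)
  for (k in seq_len(iterations)) {
    B <- filter_band(sp, f0, radius, 0.1 * radius, demodulate = TRUE)
    B <- B[ri, ci]
    dx <- Arg(B[, -1] * Conj(B[, -ncol(B)]))
    dy <- Arg(B[-1, ] * Conj(B[-nrow(B), ]))
    f0 <- f0 + c(stats::median(dx), stats::median(dy)) / (2 * pi)
  }
  f0
}

# shared band extraction core: soft mask around `center`, optional
# translation of the band to DC (integer bin roll + residual-carrier ramp)
filter_band <- function(sp, center, radius, soft_edge, demodulate) {
  mask <- radial_mask(sp$shape, center, radius, soft_edge)
  Sm <- sp$S * mask
  if (!demodulate) return(ifft2(ifftshift(Sm)))
  dc_r <- floor(sp$shape[1] / 2) + 1L
  dc_c <- floor(sp$shape[2] / 2) + 1L
  br <- round(center[2] * sp$shape[1])
  bc <- round(center[1] * sp$shape[2])
  Sm <- roll_matrix(Sm, -br, -bc)
  img <- ifft2(ifftshift(Sm))
  res_fy <- center[2] - br / sp$shape[1]
  res_fx <- center[1] - bc / sp$shape[2]
  if (res_fx != 0 || res_fy != 0) {
    g <- pixel_grids(sp$shape)
    img <- img * exp(-2i * pi * (res_fx * g$x + res_fy * g$y))
  }
  img
}

#' Extract and demodulate the holographic cross band
#'
#' Applies a soft circular mask around the carrier, translates the band
#' to DC (integer-bin shift plus a residual-carrier phase ramp for the
#' subpixel remainder) and inverse-transforms. The result approximates
#' the complex product of object and conjugate reference waves; its
#' argument is the wrapped object phase.
#'
#' @param spectrum A `dhm_spectrum`.
#' @param center Band centre `c(fx, fy)` in cycles/px (from
#'   [locate_carrier()]).
#' @param radius Mask radius in cycles/px. Default:
#'   `min(coherent pupil cutoff, 0.5 * |carrier|)`, the largest passband
#'   that cannot overlap the autocorrelation band.
#' @param soft_edge Raised-cosine edge width (default 10% of the radius).
#' @return Complex baseband image.
#' @export
extract_cross_band <- function(spectrum, center, radius = NULL,
                               soft_edge = NULL) {
  sp <- as_spectrum(spectrum)
  cmag <- sqrt(sum(center^2))
  if (is.null(radius)) {
    if (is.null(sp$config))
      stop("radius must be given when the spectrum has no attached config")
    radius <- min(pupil_cutoffs_px(sp$config)[["coherent"]], 0.5 * cmag)
  }
  if (radius <= 0) stop("mask radius must be > 0")
  if (is.null(soft_edge)) soft_edge <- 0.1 * radius
  if (abs(center[1]) + radius > 0.5 + 1e-9 ||
      abs(center[2]) + radius > 0.5 + 1e-9)
    stop("cross-band mask extends beyond the Nyquist square")
  if (cmag < radius)
    warning("cross-band mask overlaps DC: band bleed likely")
  filter_band(sp, center, radius, soft_edge, demodulate = TRUE)
}

#' Extract the central (bright-field + autocorrelation) band
#'
#' Applies a soft circular mask to the central spectral region, which
#' contains the bright-field spectrum and the holographic
#' autocorrelation term, and returns the magnitude of the inverse
#' transform.
#'
#' @param spectrum A `dhm_spectrum`.
#' @param radius Mask radius, cycles/px.
#' @param soft_edge Raised-cosine edge width (default 10% of radius).
#' @param carrier Optional carrier `c(fx, fy)` (cycles/px); when given
#'   together with `cross_radius`, the mask is checked against bleeding
#'   into the cross bands.
#' @param cross_radius Cross-band radius used for the overlap check.
#' @return Magnitude image `|A|` on the gray-level scale of the input.
#' @export
extract_central_band <- function(spectrum, radius, soft_edge = NULL,
                                 carrier = NULL, cross_radius = NULL) {
  sp <- as_spectrum(spectrum)
  if (radius <= 0) stop("mask radius must be > 0")
  if (is.null(soft_edge)) soft_edge <- 0.1 * radius
  if (!is.null(carrier) && !is.null(cross_radius)) {
    cmag <- sqrt(sum(carrier^2))
    if (radius > cmag - cross_radius + 1e-9)
      stop("central-band radius ", signif(radius, 4),
           " overlaps the cross band at |carrier| ", signif(cmag, 4),
           " minus cross radius ", signif(cross_radius, 4))
  }
  Mod(filter_band(sp, c(0, 0), radius, soft_edge, demodulate = FALSE))
}
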