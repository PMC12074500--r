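#' Weighted subtraction of the cross band from the central band
#'
#' The central-band magnitude contains the bright-field image plus the
#' holographic autocorrelation terms; subtracting the weighted
#' cross-band magnitude, `BFI = |A| - w * B` with `w` in \[0, 1\],
#' minimizes the coherent contribution. Results are clipped at zero to
#' guard against noise-induced small negatives.
#'
#' @param A_mag Central-band magnitude image.
#' @param B_mag Cross-band magnitude image (same shape and gray scale).
#' @param w Weight factor in \[0, 1\].
#' @return Recovered bright-field image (nonnegative).
#' @export
weighted_subtract <- function(A_mag, B_mag, w) {
  if (!all(dim(A_mag) == dim(B_mag)))
    stop("A_mag and B_mag must have the same shape")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  pmax(A_mag - w * B_mag, 0)
}

#' Background standard deviation over declared sample-free regions
#'
#' Population standard deviation (divisor n, not n-1) over the union of
#' the ROI pixels — the background-noise metric used to score recovered
#' bright-field and phase images.
#'
#' @param image Numeric matrix.
#' @param rois A [background_rois()].
#' @return Scalar STD in the units of `image`.
#' @export
background_std <- function(image, rois) {
  mask <- roi_mask(rois, dim(image))
  px <- image[mask]
  if (!length(px)) stop("background ROI union is empty")
  sqrt(mean((px - mean(px))^2))
}

background_mean <- function(image, rois) {
  mean(image[roi_mask(rois, dim(image))])
}

#' Optimize the subtraction weight by background-noise minimization
#'
#' Evaluates `background_std(weighted_subtract(A, B, w))` over a grid of
#' weights and returns the minimizer together with the full STD curve.
#' Ties are broken toward the smaller weight (less subtraction).
#'
#' @param A_mag,B_mag Central- and cross-band magnitude images.
#' @param rois A [background_rois()].
#' @param grid Weight grid in \[0, 1\], at least 3 points; default
#'   0 to 1 in steps of 0.05.
#' @return List with `w_opt` and `std_curve` (data.frame of `w`, `std`).
#' @export
optimize_w <- function(A_mag, B_mag, rois, grid = seq(0, 1, by = 0.05)) {
  if (length(grid) < 3) stop("the weight grid needs at least 3 points")
  if (any(grid < 0 | grid > 1)) stop("the weight grid must lie in [0, 1]")
  grid <- sort(grid)
  stds <- vapply(grid, function(w)
    background_std(weighted_subtract(A_mag, B_mag, w), rois), numeric(1))
  # which.min returns the first minimum; with an ascending grid that is
  # the smaller-w tie-break
  list(w_opt = grid[which.min(stds)],
       std_curve = data.frame(w = grid, std = stds))
}

#' Recover the noise-reduced bright-field image
#'
#' Bright-field branch of the demultiplexing pipeline: spectrum, carrier
#' location, central-band magnitude `|A|`, cross-band magnitude `B`
#' (both on the same gray scale, as produced by the same spectrum), and
#' weighted subtraction with either a fixed weight or the
#' background-STD-minimizing weight.
#'
#' @param image A `multiplexed_image` (or matrix plus `config`).
#' @param config Optics configuration; taken from the image if omitted.
#' @param w Fixed weight; if `NULL` (default) the weight is optimized on
#'   `grid`.
#' @param grid Weight grid for [optimize_w()].
#' @param rois Background ROIs (default [corner_rois()]).
#' @param cross_radius Cross-band mask radius, cycles/px (default as in
#'   [extract_cross_band()]).
#' @param central_radius Central-band radius (default: equal to the
#'   cross-band radius; must not bleed into the cross bands).
#' @param soft_edge Mask edge width (default 10% of each radius).
#' @return An object of class `bf_result`: `$A_mag`, `$B_mag`, `$w`,
#'   `$bfi`, `$std_curve`, `$w_opt`, `$carrier`, `$rois`.
#' @export
reconstruct_bf <- function(image, config = NULL, w = NULL,
                           grid = seq(0, 1, by = 0.05), rois = NULL,
                           cross_radius = NULL, central_radius = NULL,
                           soft_edge = NULL) {
  if (inherits(image, "multiplexed_image") && is.null(config))
    config <- image$config
  if (is.null(config)) stop("an optics config is required")
  sp <- compute_spectrum(image)
  sp$config <- config
  car <- locate_carrier(sp)
  cmag <- sqrt(sum(car$f_px^2))
  prelim <- if (is.null(cross_radius))
    min(pupil_cutoffs_px(config)[["coherent"]], 0.5 * cmag) else cross_radius
  car$f_px <- refine_carrier(sp, car$f_px, prelim)
  cmag <- sqrt(sum(car$f_px^2))
  if (is.null(cross_radius))
    cross_radius <- min(pupil_cutoffs_px(config)[["coherent"]], 0.5 * cmag)
  # symmetric bands by default, shrunk if the refined carrier sits closer
  # than two radii from DC
  if (is.null(central_radius))
    central_radius <- min(cross_radius, cmag - cross_radius)
  A <- extract_central_band(sp, central_radius, soft_edge,
                            carrier = car$f_px, cross_radius = cross_radius)
  B <- Mod(extract_cross_band(sp, car$f_px, cross_radius, soft_edge))
  if (is.null(rois)) rois <- corner_rois(dim(A))
  opt <- optimize_w(A, B, rois, grid)
  w_used <- if (is.null(w)) opt$w_opt else w
  structure(list(
    A_mag = A, B_mag = B, w = w_used, bfi = weighted_subtract(A, B, w_used),
    std_curve = opt$std_curve, w_opt = opt$w_opt, carrier = car,
    cross_radius = cross_radius, central_radius = central_radius,
    rois = rois
  ), class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bf_result> %d x %d px, w = %.2f (w_opt = %.2f)\n",
              nrow(x$bfi), ncol(x$bfi), x$w, x$w_opt))
  invisible(x)
}

#' Demultiplex both imaging modes from one capture
#'
#' Convenience wrapper running [reconstruct_qpi()] and
#' [reconstruct_bf()] on a shared spectrum and carrier estimate.
#'
#' @inheritParams reconstruct_qpi
#' @inheritParams reconstruct_bf
#' @return List with `$qpi` (a `qpi_result`), `$bf` (a `bf_result`) and
#'   `$carrier`.
#' @export
demultiplex <- function(image, config = NULL, delta_n = NULL,
                        grid = seq(0, 1, by = 0.05), rois = NULL,
                        cross_radius = NULL, poly_degree = 4) {
  if (inherits(image, "multiplexed_image") && is.null(config))
    config <- image$config
  qpi <- reconstruct_qpi(image, config, delta_n = delta_n,
                         cross_radius = cross_radius, rois = rois,
                         poly_degree = poly_degree)
  bf <- reconstruct_bf(image, config, grid = grid, rois = rois,
                       cross_radius = qpi$cross_radius)
  list(qpi = qpi, bf = bf, carrier = qpi$carrier)
}
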