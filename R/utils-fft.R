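# Internal FFT and grid helpers. Convention throughout the package:
# row-major images, origin top-left; x runs along columns, y along rows;
# spectra are handled DC-centered (fftshift'ed); spatial frequencies are
# stored internally in cycles/pixel at the sensor plane and converted to
# cycles/m via the pixel pitch only at user-facing interfaces.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @noRd
shift_index <- function(n, inverse = FALSE) {
  h <- if (inverse) floor(n / 2) else ceiling(n / 2)
  (seq_len(n) - 1L + h) %% n + 1L
}

fftshift <- function(m) m[shift_index(nrow(m)), shift_index(ncol(m)), drop = FALSE]

ifftshift <- function(m) {
  m[shift_index(nrow(m), inverse = TRUE), shift_index(ncol(m), inverse = TRUE),
    drop = FALSE]
}

# DC-centered frequency axis in cycles/px; DC sits at index floor(n/2)+1.
freq_axis <- function(n) (seq_len(n) - 1L - floor(n / 2)) / n

# fx varies along columns, fy along rows (both cycles/px, DC-centered).
freq_grids <- function(shape) {
  list(
    fx = matrix(freq_axis(shape[2]), shape[1], shape[2], byrow = TRUE),
    fy = matrix(freq_axis(shape[1]), shape[1], shape[2])
  )
}

# Pixel coordinate grids (0-based), x along columns, y along rows.
pixel_grids <- function(shape) {
  list(
    x = matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE),
    y = matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  )
}

# Soft-edged circular mask over a DC-centered frequency plane.
# Unity inside radius - soft_edge, raised-cosine (Tukey) taper to zero at
# radius. center is c(fx, fy) in cycles/px.
radial_mask <- function(shape, center, radius, soft_edge = 0) {
  g <- freq_grids(shape)
  rho <- sqrt((g$fx - center[1])^2 + (g$fy - center[2])^2)
  if (soft_edge <= 0) {
    return((rho <= radius) * 1)
  }
  m <- matrix(0, shape[1], shape[2])
  inner <- radius - soft_edge
  m[rho <= inner] <- 1
  taper <- rho > inner & rho < radius
  m[taper] <- 0.5 * (1 + cos(pi * (rho[taper] - inner) / soft_edge))
  m
}

hann2 <- function(shape) {
  wr <- 0.5 * (1 - cos(2 * pi * (seq_len(shape[1]) - 1) / (shape[1] - 1)))
  wc <- 0.5 * (1 - cos(2 * pi * (seq_len(shape[2]) - 1) / (shape[2] - 1)))
  outer(wr, wc)
}

# Circular roll of a matrix by (dr, dc); positive shifts move content down/right.
roll_matrix <- function(m, dr, dc) {
  r <- nrow(m); c <- ncol(m)
  dr <- ((dr %% r) + r) %% r
  dc <- ((dc %% c) + c) %% c
  ri <- ((seq_len(r) - 1L - dr) %% r) + 1L
  ci <- ((seq_len(c) - 1L - dc) %% c) + 1L
  m[ri, ci, drop = FALSE]
}

# Run fn with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}
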