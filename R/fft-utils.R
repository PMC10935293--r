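# Centered-layout unitary 2-D FFT helpers.
#
# All frequency-domain arrays in this package use the "centered" layout:
# the zero-frequency sample sits at index (floor(n/2) + 1) along each axis,
# so pupil windows are contiguous sub-matrices. Transforms are unitary
# (scaled by 1/sqrt(N)), which makes Parseval's identity exact and keeps
# adjoints equal to inverses.

#' @keywords internal
fftshift2 <- function(x) {
  d <- dim(x)
  s1 <- ceiling(d[1] / 2)
  s2 <- ceiling(d[2] / 2)
  x[c(seq_len(d[1] - s1) + s1, seq_len(s1)),
    c(seq_len(d[2] - s2) + s2, seq_len(s2)), drop = FALSE]
}

#' @keywords internal
ifftshift2 <- function(x) {
  d <- dim(x)
  s1 <- floor(d[1] / 2)
  s2 <- floor(d[2] / 2)
  x[c(seq_len(d[1] - s1) + s1, seq_len(s1)),
    c(seq_len(d[2] - s2) + s2, seq_len(s2)), drop = FALSE]
}

#' Unitary centered 2-D Fourier transform
#'
#' Forward (`fft2c`) and inverse (`ifft2c`) discrete Fourier transforms
#' with zero frequency at the grid center and unitary normalization
#' (division by the square root of the number of samples in each
#' direction of the transform pair), so `ifft2c(fft2c(x))` reproduces `x`
#' and total energy is preserved.
#'
#' @param x a numeric or complex matrix (space-domain for `fft2c`,
#'   centered frequency-domain for `ifft2c`).
#' @return a complex matrix of the same dimensions.
#' @examples
#' x <- matrix(rnorm(16), 4, 4)
#' max(Mod(ifft2c(fft2c(x)) - x)) < 1e-12
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

# Index of the zero-frequency (and spatial-origin) pixel in centered layout.
#' @keywords internal
center_index <- function(n) floor(n / 2) + 1L

# Centered frequency coordinate grids (cycles/unit) for an n1 x n2 matrix
# sampled at pitch `dx`; rows vary along y, columns along x.
#' @keywords internal
freq_grid <- function(shape, dk) {
  n1 <- shape[1]; n2 <- shape[2]
  fy <- (seq_len(n1) - center_index(n1)) * dk
  fx <- (seq_len(n2) - center_index(n2)) * dk
  list(kx = matrix(fx, n1, n2, byrow = TRUE),
       ky = matrix(fy, n1, n2, byrow = FALSE))
}

# Row/column ranges of an m1 x m2 window whose center pixel lands on the
# (center + offset) pixel of an M1 x M2 centered grid. offset = c(row, col).
#' @keywords internal
window_ranges <- function(big_shape, small_shape, offset = c(0L, 0L)) {
  r0 <- center_index(big_shape[1]) + offset[1] - center_index(small_shape[1])
  c0 <- center_index(big_shape[2]) + offset[2] - center_index(small_shape[2])
  rows <- r0 + seq_len(small_shape[1])
  cols <- c0 + seq_len(small_shape[2])
  if (rows[1] < 1L || cols[1] < 1L ||
      rows[length(rows)] > big_shape[1] || cols[length(cols)] > big_shape[2]) {
    stop("spectrum window (offset ", offset[1], ",", offset[2],
         ") falls outside the high-resolution frequency grid", call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

#' Upsample a complex field by Fourier zero-padding
#'
#' Embeds the centered spectrum of `x` in a larger zero-filled frequency
#' grid and inverse-transforms. With the unitary convention used here the
#' embedded spectrum is not rescaled, so a field whose spectrum was
#' produced by pupil-window cropping of a high-resolution spectrum is
#' restored to the original amplitude scale.
#'
#' @param x numeric or complex matrix.
#' @param factor integer upsampling factor (\eqn{\ge} 1).
#' @return complex matrix with `factor` times the rows and columns of `x`.
#' @export
upsample_fourier <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(x + 0i)
  d <- dim(x)
  big <- d * factor
  spec <- matrix(0 + 0i, big[1], big[2])
  w <- window_ranges(big, d)
  spec[w$rows, w$cols] <- fft2c(x)
  ifft2c(spec)
}
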