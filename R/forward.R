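# Forward imaging model: shifted object spectrum -> pupil low-pass ->
# inverse transform -> intensity on the detector grid.
#
# Oblique illumination with wave vector k_n multiplies the object by a
# tilted plane wave, shifting its spectrum to O(k - k_n); the objective
# then passes the pupil disk around zero frequency. On the discrete grids
# this is a contiguous window of the high-resolution centered spectrum at
# integer-pixel offset -round(k_n / dk); the sub-pixel quantization
# residual is recorded for diagnostics. Cropping the frequency window to
# the low-resolution grid size implements detector downsampling
# (Fourier-domain decimation).

# Integer pixel shift (rows, cols) and residual for a wave vector.
#' @keywords internal
quantize_shift <- function(k_n, dk) {
  px <- k_n / dk                       # (kx, ky) in pixels
  s <- round(px)
  list(offset = c(-s[2], -s[1]), residual = px - s)  # (row, col) offset
}

#' Shift an object spectrum by an illumination wave vector
#'
#' Returns O(k - k_n) with the shift quantized to the nearest integer
#' pixel of the centered frequency grid (circular roll). The sub-pixel
#' quantization residual, in pixels, is attached as attribute
#' `"residual"`.
#'
#' @param spectrum a frequency-domain [complex_field] or complex matrix.
#' @param k_n illumination wave vector (kx, ky), cycles/um.
#' @param dk frequency pitch of the grid, cycles/um; taken from the
#'   field's `sampling` when omitted.
#' @return object of the same kind as `spectrum`, shifted.
#' @export
shift_spectrum <- function(spectrum, k_n, dk = NULL) {
  is_field <- inherits(spectrum, "complex_field")
  if (is_field) {
    stopifnot(spectrum$domain == "frequency")
    if (is.null(dk)) dk <- spectrum$sampling
  }
  if (is.null(dk)) stop("frequency pitch `dk` is required", call. = FALSE)
  v <- field_values(spectrum)
  q <- quantize_shift(k_n, dk)
  d <- dim(v)
  # O(k - k_n): the value at index i is read from i - s = i + offset
  ri <- ((seq_len(d[1]) - 1L + q$offset[1]) %% d[1]) + 1L
  ci <- ((seq_len(d[2]) - 1L + q$offset[2]) %% d[2]) + 1L
  out <- v[ri, ci, drop = FALSE]
  attr(out, "residual") <- q$residual
  if (is_field) {
    f <- complex_field(out, "frequency", dk)
    attr(f, "residual") <- q$residual
    f
  } else out
}

# Extract the pupil-window submatrix of a high-res centered spectrum for
# wave vector k_n (offset -round(k_n/dk)); errors if it leaves the grid.
#' @keywords internal
spectrum_window <- function(S, k_n, dk, lores_shape) {
  q <- quantize_shift(k_n, dk)
  w <- window_ranges(dim(S), lores_shape, q$offset)
  list(values = S[w$rows, w$cols, drop = FALSE], rows = w$rows,
       cols = w$cols, residual = q$residual)
}

#' Simulate one low-resolution intensity image
#'
#' The FPM forward model for a single LED: crop the pupil window of the
#' (shifted) high-resolution object spectrum, multiply by the complex
#' pupil, inverse-transform to the detector plane, and detect the squared
#' modulus.
#'
#' @param object_spectrum high-resolution centered spectrum
#'   ([complex_field] in the frequency domain, or a complex matrix).
#' @param pupil an [fpm_pupil] (or complex matrix) on the low-res grid.
#' @param k_n illumination wave vector (kx, ky), cycles/um.
#' @param system an [fpm_system].
#' @return non-negative intensity matrix on the low-resolution grid.
#' @export
forward_image <- function(object_spectrum, pupil, k_n, system) {
  S <- field_values(object_spectrum)
  P <- if (inherits(pupil, "fpm_pupil")) pupil$values else pupil
  if (!all(dim(P) == system$lores_shape))
    stop("pupil grid ", paste(dim(P), collapse = "x"),
         " does not match the low-resolution grid ",
         paste(system$lores_shape, collapse = "x"), call. = FALSE)
  win <- spectrum_window(S, k_n, system$dk, system$lores_shape)
  g <- ifft2c(win$values * P)
  Mod(g)^2
}

#' Noise specification for simulated acquisitions
#'
#' @param photons expected photon count at unit intensity for Poisson
#'   shot noise, or `NULL` to disable.
#' @param read_sd Gaussian read-noise standard deviation (intensity
#'   units), or 0 to disable.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(photons = NULL, read_sd = 0) {
  stopifnot(is.null(photons) || photons > 0, read_sd >= 0)
  structure(list(photons = photons, read_sd = read_sd),
            class = "noise_spec")
}

#' Simulate a full FPM acquisition stack
#'
#' Generates one low-resolution intensity image per LED, in scan order;
#' a 15 x 15 array yields 225 images. Noise is off by default (shot and
#' read noise can be enabled through [noise_spec()]); when enabled the
#' supplied seed makes the stack reproducible.
#'
#' @param object space-domain [complex_field] (or complex matrix) on the
#'   high-resolution grid.
#' @param pupil an [fpm_pupil] on the low-resolution grid.
#' @param leds an [led_array].
#' @param system an [fpm_system].
#' @param noise a [noise_spec()] or `NULL` for a noiseless acquisition.
#' @param seed integer RNG seed used if noise is enabled.
#' @return an object of class `fpm_stack`: `images` (rows x cols x n
#'   array), `wavevectors`, per-LED quantization `residuals`, and the
#'   provenance (`system`, `leds`, `noise`, `seed`).
#' @export
simulate_dataset <- function(object, pupil, leds, system, noise = NULL,
                             seed = NULL) {
  ov <- field_values(object)
  if (!all(dim(ov) == system$hires_shape))
    stop("object must live on the high-resolution grid", call. = FALSE)
  S <- fft2c(ov)
  n <- nrow(leds$wavevectors)
  m <- system$lores_shape
  imgs <- array(0, c(m[1], m[2], n))
  resid <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    idx <- leds$scan_order[i]
    k_n <- leds$wavevectors[idx, ]
    I <- tryCatch(forward_image(S, pupil, k_n, system),
                  error = function(e)
                    stop("LED ", idx, ": ", conditionMessage(e),
                         call. = FALSE))
    imgs[, , i] <- I
    resid[i, ] <- quantize_shift(k_n, system$dk)$residual
  }
  if (!is.null(noise) && (!is.null(noise$photons) || noise$read_sd > 0)) {
    if (!is.null(seed)) set.seed(seed)
    if (!is.null(noise$photons))
      imgs[] <- stats::rpois(length(imgs), imgs * noise$photons) /
        noise$photons
    if (noise$read_sd > 0)
      imgs[] <- imgs + stats::rnorm(length(imgs), sd = noise$read_sd)
    imgs[imgs < 0] <- 0
  }
  structure(list(images = imgs,
                 wavevectors = leds$wavevectors[leds$scan_order, ,
                                                drop = FALSE],
                 residuals = resid, system = system, leds = leds,
                 noise = noise, seed = seed),
            class = "fpm_stack")
}

#' @export
print.fpm_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<fpm_stack> %d images of %d x %d\n", d[3], d[1], d[2]))
  bf <- sum(sqrt(rowSums(x$wavevectors^2)) < x$system$cutoff)
  cat(sprintf("  %d bright-field / %d dark-field LEDs, %s\n", bf, d[3] - bf,
              if (is.null(x$noise)) "noiseless"
              else sprintf("noisy (seed %s)", x$seed)))
  invisible(x)
}
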