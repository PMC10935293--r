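# Classical FPM reconstruction: alternating projections that stitch the
# pupil windows of the high-resolution spectrum together, enforcing the
# measured intensity in the image domain (Gerchberg-Saxton-style
# magnitude replacement). This serves as the no-aberration-correction
# baseline: the pupil is supplied and held fixed.

#' Low-resolution field estimate for one LED
#'
#' g_n(r) = F^-1 { p(k) * O(k - k_n) } evaluated on the low-resolution
#' grid from the current high-resolution spectrum estimate.
#'
#' @param spectrum high-resolution centered spectrum (matrix or
#'   frequency-domain [complex_field]).
#' @param pupil an [fpm_pupil] or complex matrix on the low-res grid.
#' @param k_n illumination wave vector, cycles/um.
#' @param system an [fpm_system].
#' @return complex matrix on the low-resolution grid.
#' @export
estimate_lowres <- function(spectrum, pupil, k_n, system) {
  S <- field_values(spectrum)
  P <- if (inherits(pupil, "fpm_pupil")) pupil$values else pupil
  win <- spectrum_window(S, k_n, system$dk, system$lores_shape)
  ifft2c(win$values * P)
}

#' Magnitude-replacement spectrum update for one LED
#'
#' Replaces the modulus of the current low-resolution field estimate with
#' the square root of the measured intensity, keeps its phase (zero where
#' the modulus vanishes), transforms back, and writes the result into the
#' pupil window of the high-resolution spectrum. Inside the pupil support
#' the stored spectrum patch becomes F{g'} / p(k), which removes the
#' known pupil factor; pixels outside the support are untouched.
#'
#' @param spectrum high-resolution centered spectrum (complex matrix).
#' @param pupil an [fpm_pupil] or complex matrix.
#' @param k_n illumination wave vector, cycles/um.
#' @param measured non-negative measured intensity, low-res grid.
#' @param system an [fpm_system].
#' @return the updated high-resolution spectrum matrix.
#' @export
spectrum_update <- function(spectrum, pupil, k_n, measured, system) {
  if (any(measured < 0))
    stop("measured intensities must be non-negative", call. = FALSE)
  S <- field_values(spectrum)
  P <- if (inherits(pupil, "fpm_pupil")) pupil$values else pupil
  win <- spectrum_window(S, k_n, system$dk, system$lores_shape)
  g <- ifft2c(win$values * P)
  # Arg(0+0i) is 0 in R, so zero-modulus pixels keep phase 0 (no NaN)
  g_new <- sqrt(measured) * exp(1i * Arg(g))
  phi <- fft2c(g_new)
  upd <- abs(P) > 1e-12
  patch <- win$values
  patch[upd] <- phi[upd] / P[upd]
  S[win$rows, win$cols] <- patch
  S
}

#' Classical iterative FPM reconstruction (no aberration correction)
#'
#' Sweeps all LEDs per iteration, applying [estimate_lowres()] and
#' [spectrum_update()] with a fixed, supplied pupil (the ideal CTF for
#' the uncorrected baseline, or a known aberrated pupil). Initialization
#' is the Fourier-zero-padding upsampled square root of the most axial
#' LED's image (`init = "lowres"`) or a flat unit spectrum
#' (`init = "ones"`). Stops after `n_iters` sweeps or when the relative
#' spectrum change drops below `tol`.
#'
#' @param stack an `fpm_stack`.
#' @param system an [fpm_system]; defaults to the stack's.
#' @param pupil an [fpm_pupil]; defaults to the ideal binary CTF.
#' @param n_iters maximum number of full sweeps (>= 0; 0 returns the
#'   initialization).
#' @param init `"lowres"` or `"ones"`.
#' @param tol relative spectrum-change stopping tolerance.
#' @return a list of class `fpm_classic`: `object` (space-domain
#'   [complex_field]), `spectrum`, `iterations`, `trace` (data frame with
#'   per-sweep relative spectrum change and intensity misfit).
#' @export
reconstruct_classic <- function(stack, system = stack$system,
                                pupil = NULL, n_iters = 50L,
                                init = c("lowres", "ones"), tol = 1e-6) {
  init <- match.arg(init)
  if (n_iters < 0L) stop("n_iters must be >= 0", call. = FALSE)
  basis <- zernike_basis(system, zernike_terms(0L))
  if (is.null(pupil))
    pupil <- build_pupil(make_ctf(system), basis)
  M <- system$hires_shape
  S <- if (init == "ones") {
    matrix(1 + 0i, M[1], M[2])
  } else {
    ctr <- which.min(rowSums(stack$wavevectors^2))
    lo <- sqrt(stack$images[, , ctr])
    big <- matrix(0 + 0i, M[1], M[2])
    w <- window_ranges(M, dim(lo))
    big[w$rows, w$cols] <- fft2c(lo)
    big
  }
  n_led <- dim(stack$images)[3]
  trace <- data.frame(sweep = integer(0), rel_change = numeric(0),
                      misfit = numeric(0))
  it <- 0L
  while (it < n_iters) {
    it <- it + 1L
    S_old <- S
    for (i in seq_len(n_led)) {
      S <- spectrum_update(S, pupil, stack$wavevectors[i, ],
                           stack$images[, , i], system)
    }
    rel <- sqrt(sum(Mod(S - S_old)^2)) / max(sqrt(sum(Mod(S_old)^2)), 1e-30)
    mis <- 0
    for (i in seq_len(n_led)) {
      g <- estimate_lowres(S, pupil, stack$wavevectors[i, ], system)
      mis <- mis + sum((Mod(g)^2 - stack$images[, , i])^2)
    }
    trace <- rbind(trace, data.frame(sweep = it, rel_change = rel,
                                     misfit = mis))
    if (rel < tol) break
  }
  obj <- ifft2c(S)
  structure(list(object = complex_field(obj, "space",
                                        system$pixel_size_obj),
                 spectrum = complex_field(S, "frequency", system$dk),
                 pupil = pupil, iterations = it, trace = trace),
            class = "fpm_classic")
}
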