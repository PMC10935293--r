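# Synthetic phantoms and benchmark scenarios. Emulates a defocused FPM
# acquisition: a complex object with independent amplitude and phase
# patterns (in place of standard test photographs, which are accepted
# from file but never bundled), an aberrated pupil with a calibrated
# defocus Zernike phase, and the full simulated intensity stack.

# Deterministic scalar [0,1] pattern generators -----------------------------

#' @keywords internal
pattern01 <- function(pattern, shape, seed) {
  n1 <- shape[1]; n2 <- shape[2]
  xs <- matrix(seq_len(n2), n1, n2, byrow = TRUE) / n2
  ys <- matrix(seq_len(n1), n1, n2) / n1
  if (file.exists(pattern)) return(read_image01(pattern, shape))
  set.seed(seed)
  out <- switch(pattern,
    checker = {
      cells <- 8L
      ((floor(xs * cells) + floor(ys * cells)) %% 2)
    },
    blobs = {
      # smoothed Gaussian random field
      z <- matrix(stats::rnorm(n1 * n2), n1, n2)
      g <- freq_grid(shape, 1 / n1)
      filt <- exp(-(g$kx^2 + g$ky^2) / (2 * (2.5 / n1)^2))
      sm <- Re(ifft2c(fft2c(z) * filt))
      normalize01(sm)
    },
    stripes = {
      # text-like bars: thresholded two-tone stripes at a random angle
      ang <- stats::runif(1, 0, pi)
      f1 <- stats::runif(1, 4, 7)
      f2 <- stats::runif(1, 9, 13)
      u <- xs * cos(ang) + ys * sin(ang)
      v <- -xs * sin(ang) + ys * cos(ang)
      s <- sin(2 * pi * f1 * u) + 0.6 * sin(2 * pi * f2 * v)
      (s > 0) * 1
    },
    stop("unknown phantom pattern: ", pattern, call. = FALSE)
  )
  # soften pattern edges (~1.5 px Gaussian): emulates photographic test
  # images, whose energy sits at scales the synthesized aperture resolves
  if (pattern %in% c("checker", "stripes")) out <- smooth_gauss(out, 1.5)
  out
}

# Gaussian blur by Fourier multiplication (sigma in pixels).
#' @keywords internal
smooth_gauss <- function(x, sigma) {
  g <- freq_grid(dim(x), 1)        # integer pixel frequencies
  kx <- g$kx / ncol(x); ky <- g$ky / nrow(x)   # cycles per pixel
  filt <- exp(-2 * pi^2 * sigma^2 * (kx^2 + ky^2))
  Re(ifft2c(fft2c(x) * filt))
}

# Grayscale image file -> [0,1] matrix resampled to `shape` (nearest).
#' @keywords internal
read_image01 <- function(path, shape) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png" && requireNamespace("png", quietly = TRUE)) {
    png::readPNG(path)
  } else stop("unsupported image format: ", path, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  ri <- round(seq(1, nrow(img), length.out = shape[1]))
  ci <- round(seq(1, ncol(img), length.out = shape[2]))
  normalize01(img[ri, ci])
}

#' Phantom specification
#'
#' Describes a synthetic complex object: independent amplitude and phase
#' patterns (so the two carry uncorrelated structure, as when distinct
#' photographs are used for each), an amplitude range inside (0, 1], and
#' a phase range [-pi s, pi s].
#'
#' @param shape (rows, cols) of the high-resolution grid; scalar means
#'   square.
#' @param amplitude_pattern `"checker"`, `"blobs"`, `"stripes"`, or a
#'   path to a grayscale TIFF/PNG.
#' @param phase_pattern same choices, independent of the amplitude.
#' @param amplitude_range length-2 numeric in (0, 1].
#' @param phase_scale s in [0, 1]: phase spans [-pi s, pi s].
#' @param seed integer; the phantom is deterministic given the seed.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L),
                         amplitude_pattern = "blobs",
                         phase_pattern = "stripes",
                         amplitude_range = c(0.2, 1),
                         phase_scale = 0.5, seed = 1L) {
  if (length(shape) == 1L) shape <- rep(shape, 2L)
  stopifnot(amplitude_range[1] > 0, amplitude_range[2] <= 1,
            amplitude_range[1] <= amplitude_range[2],
            phase_scale >= 0, phase_scale <= 1)
  structure(list(shape = as.integer(shape),
                 amplitude_pattern = amplitude_pattern,
                 phase_pattern = phase_pattern,
                 amplitude_range = amplitude_range,
                 phase_scale = phase_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a complex phantom object
#'
#' @param spec a [phantom_spec()].
#' @return a space-domain [complex_field] whose modulus lies in the
#'   requested amplitude range and whose phase lies in
#'   [-pi s, pi s].
#' @export
make_phantom <- function(spec = phantom_spec()) {
  amp01 <- pattern01(spec$amplitude_pattern, spec$shape, spec$seed)
  ph01 <- pattern01(spec$phase_pattern, spec$shape, spec$seed + 1000L)
  lo <- spec$amplitude_range[1]; hi <- spec$amplitude_range[2]
  amp <- lo + (hi - lo) * amp01
  phase <- pi * spec$phase_scale * (2 * ph01 - 1)
  complex_field(amp * exp(1i * phase), "space")
}

#' Defocus-aberrated pupil
#'
#' Ideal binary CTF amplitude with the defocus Zernike phase implied by
#' a defocus plane z: the (n = 2, m = 0) coefficient comes from
#' [defocus_to_zernike()] (about -1.48 rad at z = 50 um, NA = 0.1,
#' lambda = 532 nm).
#'
#' @param z defocus distance, micrometres (0 gives the ideal CTF).
#' @param system an [fpm_system].
#' @param n_max Zernike radial order of the basis carried by the pupil.
#' @param model defocus phase model, see [defocus_to_zernike()].
#' @return an [build_pupil] object.
#' @export
make_defocus_scenario <- function(z, system, n_max = 4L,
                                  model = "paraxial") {
  basis <- zernike_basis(system, zernike_terms(n_max))
  coeffs <- numeric(nrow(basis$terms))
  idx <- which(basis$terms$n == 2L & basis$terms$m == 0L)
  coeffs[idx] <- defocus_to_zernike(z, system, model)
  build_pupil(make_ctf(system), basis, coeffs)
}

#' Reproducible defocused benchmark case
#'
#' Packages one full simulated experiment: ground-truth phantom, the
#' true (defocus-aberrated) pupil, and the acquisition stack, with all
#' parameters recorded. Two calls with equal arguments give bit-equal
#' stacks.
#'
#' @param z defocus distance, micrometres.
#' @param spec a [phantom_spec()]; its shape must match the system.
#' @param leds an [led_array].
#' @param system an [fpm_system].
#' @param noise a [noise_spec()] or `NULL`.
#' @param seed integer seed (phantom and noise).
#' @return list of class `fpm_benchmark` with `truth`, `pupil`, `stack`,
#'   and the generating parameters.
#' @export
make_benchmark_case <- function(z = 50, spec = NULL,
                                leds = led_array(c(9L, 9L), pitch = 7),
                                system = fpm_system(), noise = NULL,
                                seed = 1L) {
  if (is.null(spec)) spec <- phantom_spec(system$hires_shape, seed = seed)
  if (!all(spec$shape == system$hires_shape))
    stop("phantom shape must match the system's high-resolution grid",
         call. = FALSE)
  truth <- make_phantom(spec)
  pupil <- make_defocus_scenario(z, system)
  stack <- simulate_dataset(truth, pupil, leds, system, noise = noise,
                            seed = seed)
  structure(list(truth = truth, pupil = pupil, stack = stack,
                 system = system, leds = leds, z = z, spec = spec,
                 noise = noise, seed = seed),
            class = "fpm_benchmark")
}
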