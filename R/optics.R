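#' Optical system geometry for an FPM setup
#'
#' Collects the quantities that fix the sampling of the reconstruction:
#' illumination wavelength, objective numerical aperture, the effective
#' object-plane pixel pitch of the high-resolution grid, the grid size,
#' and the upsampling factor linking the high-resolution grid to the
#' detector (low-resolution) grid. The angular wavenumber k0 = 2*pi/lambda
#' and the coherent cutoff frequency NA/lambda are derived.
#'
#' Spatial frequencies throughout the package are expressed in cycles per
#' micrometre, so the pupil cutoff is NA/lambda; k0 (rad/um) enters only
#' phase calculations such as defocus.
#'
#' @param wavelength illumination wavelength in micrometres (default
#'   0.532, a green LED).
#' @param na objective numerical aperture, in (0, 1) (default 0.1).
#' @param pixel_size_obj effective object-plane pixel pitch of the
#'   high-resolution grid, micrometres. The detector-plane pitch divided
#'   by magnification equals `pixel_size_obj * upsampling`.
#' @param hires_shape integer (rows, cols) of the high-resolution grid; a
#'   scalar is taken as square.
#' @param upsampling integer ratio of high-resolution to low-resolution
#'   grid size.
#' @return an object of class `fpm_system` with derived fields
#'   `k0` (rad/um), `cutoff` (cycles/um), `lores_shape`, and `dk`, the
#'   frequency pitch of both grids (cycles/um).
#' @examples
#' sys <- fpm_system()
#' sys$cutoff               # NA / lambda, about 0.188 cycles/um
#' @export
fpm_system <- function(wavelength = 0.532, na = 0.1,
                       pixel_size_obj = 0.32,
                       hires_shape = c(64L, 64L), upsampling = 4L) {
  if (length(hires_shape) == 1L) hires_shape <- rep(hires_shape, 2L)
  hires_shape <- as.integer(hires_shape)
  upsampling <- as.integer(upsampling)
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be positive", call. = FALSE)
  if (!(na > 0 && na < 1))
    stop("numerical aperture must lie in (0, 1)", call. = FALSE)
  if (pixel_size_obj <= 0)
    stop("pixel_size_obj must be positive", call. = FALSE)
  if (upsampling < 1L || any(hires_shape %% upsampling != 0L))
    stop("hires_shape must be divisible by upsampling", call. = FALSE)
  cutoff <- na / wavelength
  nyquist <- 1 / (2 * pixel_size_obj)
  if (cutoff >= nyquist)
    stop("pupil cutoff NA/lambda (", signif(cutoff, 4),
         " cyc/um) reaches the Nyquist frequency of the high-res grid (",
         signif(nyquist, 4), " cyc/um); decrease pixel_size_obj",
         call. = FALSE)
  structure(list(
    wavelength = wavelength, na = na,
    pixel_size_obj = pixel_size_obj,
    hires_shape = hires_shape, upsampling = upsampling,
    lores_shape = hires_shape %/% upsampling,
    k0 = 2 * pi / wavelength,
    cutoff = cutoff,
    dk = 1 / (hires_shape[1] * pixel_size_obj)
  ), class = "fpm_system")
}

#' @export
print.fpm_system <- function(x, ...) {
  cat("<fpm_system>\n",
      sprintf("  wavelength  %.3f um   NA %.3f   cutoff %.4f cyc/um\n",
              x$wavelength, x$na, x$cutoff),
      sprintf("  hires %d x %d @ %.3f um/px,  lores %d x %d (u = %d)\n",
              x$hires_shape[1], x$hires_shape[2], x$pixel_size_obj,
              x$lores_shape[1], x$lores_shape[2], x$upsampling),
      sprintf("  frequency pitch %.5f cyc/um\n", x$dk), sep = "")
  invisible(x)
}

#' Illumination wave vector of one LED
#'
#' For an LED at lateral offset (x, y) millimetres from the optical axis,
#' a distance `height` millimetres below the sample, the plane-wave
#' illumination direction has direction sines
#' sin(theta_x) = x / sqrt(x^2 + y^2 + h^2) (and likewise for y), using
#' the exact geometry rather than the small-angle x/h. The spatial
#' frequency imparted to the object spectrum is (sin(theta)/lambda) in
#' cycles per micrometre.
#'
#' @param led_offset numeric length-2, LED (x, y) offset in mm.
#' @param height sample-to-LED-plane distance in mm (> 0).
#' @param wavelength wavelength in micrometres (> 0).
#' @return numeric length-2, (kx, ky) in cycles/um.
#' @examples
#' led_wavevector(c(0, 0), 100, 0.532)        # on-axis: (0, 0)
#' led_wavevector(c(28, 0), 100, 0.532)[1]    # 0.2696/0.532
#' @export
led_wavevector <- function(led_offset, height, wavelength) {
  if (height <= 0 || wavelength <= 0)
    stop("invalid geometry: height and wavelength must be positive",
         call. = FALSE)
  r <- sqrt(sum(led_offset^2) + height^2)
  c(led_offset[1], led_offset[2]) / r / wavelength
}

#' LED array geometry and illumination wave vectors
#'
#' Builds a rectangular LED grid centered on the optical axis (plus an
#' optional offset) and computes each emitter's illumination wave vector.
#' LEDs are enumerated in raster scan order, top-left first, matching the
#' usual board firmware lighting sequence.
#'
#' @param grid_shape integer (rows, cols); a scalar is taken as square.
#' @param pitch LED center-to-center spacing, mm.
#' @param height sample-to-LED-plane distance, mm.
#' @param center_offset (dx, dy) of the array center from the axis, mm.
#' @param wavelength wavelength, micrometres.
#' @return an object of class `led_array` holding `positions` (n x 2, mm)
#'   and `wavevectors` (n x 2, cycles/um) in scan order.
#' @examples
#' leds <- led_array(c(15, 15), pitch = 4, height = 100)
#' nrow(leds$wavevectors)  # 225
#' @export
led_array <- function(grid_shape = c(15L, 15L), pitch = 4, height = 100,
                      center_offset = c(0, 0), wavelength = 0.532) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 2L)
  grid_shape <- as.integer(grid_shape)
  stopifnot(all(grid_shape >= 1L), pitch > 0, height > 0)
  rows <- seq_len(grid_shape[1]) - (grid_shape[1] + 1) / 2
  cols <- seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2
  # raster order: row-major from the top-left LED
  pos <- cbind(
    x = rep(cols, times = grid_shape[1]) * pitch + center_offset[1],
    y = rep(rows, each = grid_shape[2]) * pitch + center_offset[2]
  )
  wv <- t(apply(pos, 1L, led_wavevector,
                height = height, wavelength = wavelength))
  colnames(wv) <- c("kx", "ky")
  sines <- sqrt(rowSums(wv^2)) * wavelength
  stopifnot(all(sines <= 1))
  structure(list(grid_shape = grid_shape, pitch = pitch, height = height,
                 center_offset = center_offset, wavelength = wavelength,
                 positions = pos, wavevectors = wv,
                 scan_order = seq_len(nrow(pos))),
            class = "led_array")
}

#' @export
print.led_array <- function(x, ...) {
  cat(sprintf(
    "<led_array> %d x %d, pitch %.3g mm, height %.3g mm (%d LEDs)\n",
    x$grid_shape[1], x$grid_shape[2], x$pitch, x$height,
    nrow(x$positions)))
  cat(sprintf("  max |sin(theta)| = %.4f\n",
              max(sqrt(rowSums(x$wavevectors^2))) * x$wavelength))
  invisible(x)
}

#' Ideal coherent transfer function (binary pupil)
#'
#' The diffraction-limited coherent transfer function of the objective: a
#' disk of 1s where kx^2 + ky^2 < (NA/lambda)^2 on the centered frequency
#' grid, 0 outside.
#'
#' @param system an [fpm_system].
#' @param grid_shape integer (rows, cols) of the frequency grid; defaults
#'   to the system's low-resolution grid, where the pupil lives.
#' @return numeric 0/1 matrix.
#' @export
make_ctf <- function(system, grid_shape = system$lores_shape) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 2L)
  grid_shape <- as.integer(grid_shape)
  extent <- (grid_shape %/% 2) * system$dk
  if (any(extent < system$cutoff))
    stop("pupil cutoff ", signif(system$cutoff, 4),
         " cyc/um exceeds the frequency extent of a ",
         grid_shape[1], " x ", grid_shape[2], " grid (",
         signif(min(extent), 4), " cyc/um)", call. = FALSE)
  g <- freq_grid(grid_shape, system$dk)
  (g$kx^2 + g$ky^2 < system$cutoff^2) * 1
}

# ---------------------------------------------------------------------------
# Zernike polynomials on the unit pupil disk
# ---------------------------------------------------------------------------

#' Zernike term table
#'
#' Enumerates Zernike terms up to radial order `n_max`. Terms are listed
#' by increasing radial order n, and within an order by increasing
#' azimuthal frequency |m|; for m != 0 the cosine and sine variants are
#' both present, encoded by the sign of m (m > 0: cos(m theta),
#' m < 0: sin(|m| theta)). A running index j is attached. The (n = 2,
#' m = 0) term is defocus ("Z20").
#'
#' @param n_max maximum radial order (default 4, giving 15 terms).
#' @return data.frame with columns `j`, `n`, `m`.
#' @export
zernike_terms <- function(n_max = 4L) {
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 0L)
  out <- list()
  for (n in 0:n_max) {
    for (am in seq(n %% 2L, n, by = 2L)) {
      if (am == 0L) {
        out[[length(out) + 1L]] <- c(n, 0L)
      } else {
        out[[length(out) + 1L]] <- c(n, am)   # cos
        out[[length(out) + 1L]] <- c(n, -am)  # sin
      }
    }
  }
  tab <- do.call(rbind, out)
  data.frame(j = seq_len(nrow(tab)), n = tab[, 1], m = tab[, 2])
}

#' Radial Zernike polynomial
#'
#' Evaluates R_n^m(rho) = sum_s (-1)^s (n-s)! /
#' (s! ((n+m)/2 - s)! ((n-m)/2 - s)!) rho^(n-2s) for s = 0 ... (n-m)/2.
#' Satisfies R_n^m(1) = 1 for every valid (n, m).
#'
#' @param n radial order (integer >= 0).
#' @param m azimuthal order (integer, 0 <= m <= n, n - m even).
#' @param rho radius values in [0, 1] (vector or matrix).
#' @return numeric of the same shape as `rho`.
#' @examples
#' zernike_radial(2, 0, 0.5)   # 2*rho^2 - 1 = -0.5
#' @export
zernike_radial <- function(n, m, rho) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 0L || n < m || (n - m) %% 2L != 0L)
    stop("invalid Zernike indices: need n >= m >= 0 with n - m even",
         call. = FALSE)
  s <- 0:((n - m) %/% 2L)
  coefs <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial((n + m) %/% 2L - s) *
       factorial((n - m) %/% 2L - s))
  out <- rho * 0
  for (i in seq_along(s)) out <- out + coefs[i] * rho^(n - 2L * s[i])
  out
}

# Single Zernike polynomial Z_j on (rho, theta); m sign encodes cos/sin.
#' @keywords internal
zernike_poly <- function(n, m, rho, theta,
                         normalization = c("unit", "noll")) {
  normalization <- match.arg(normalization)
  r <- zernike_radial(n, abs(m), rho)
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
  pref <- 1
  if (normalization == "noll")
    pref <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  pref * r * ang
}

#' Zernike basis on a pupil grid
#'
#' Maps the pupil disk |k| < NA/lambda of a centered frequency grid onto
#' the unit disk via rho = |k| * lambda / NA (clipped to 1 on the
#' boundary ring) and evaluates each Zernike term there. Pixels outside
#' the pupil support evaluate to 0.
#'
#' @param system an [fpm_system].
#' @param terms a term table from [zernike_terms()].
#' @param grid_shape frequency grid size (default: low-res grid).
#' @param normalization `"unit"` for the plain polynomials (defocus is
#'   2 rho^2 - 1) or `"noll"` orthonormal prefactors (sqrt(2(n+1)) for
#'   m != 0, sqrt(n+1) for m = 0).
#' @return an object of class `zernike_basis`: list with the term table,
#'   the normalization, the support mask, and `maps`, a 3-D array
#'   (rows x cols x n_terms) of sampled polynomials.
#' @export
zernike_basis <- function(system, terms = zernike_terms(4L),
                          grid_shape = system$lores_shape,
                          normalization = c("unit", "noll")) {
  normalization <- match.arg(normalization)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 2L)
  g <- freq_grid(as.integer(grid_shape), system$dk)
  kr <- sqrt(g$kx^2 + g$ky^2)
  support <- kr < system$cutoff
  rho <- pmin(kr / system$cutoff, 1)
  theta <- atan2(g$ky, g$kx)
  maps <- array(0, c(dim(rho), nrow(terms)))
  for (i in seq_len(nrow(terms))) {
    z <- zernike_poly(terms$n[i], terms$m[i], rho, theta, normalization)
    maps[, , i] <- z * support
  }
  structure(list(terms = terms, normalization = normalization,
                 support = support, maps = maps, grid_shape = dim(rho)),
            class = "zernike_basis")
}

#' Pupil phase from Zernike coefficients
#'
#' The aberration phase sum_i c_i Z_i(rho, theta) sampled on the pupil
#' grid; zero outside the pupil support by convention. Linear in the
#' coefficient vector.
#'
#' @param basis a [zernike_basis].
#' @param coeffs numeric coefficient vector, radians, one per term.
#' @return numeric phase matrix (radians).
#' @export
zernike_phase <- function(basis, coeffs) {
  stopifnot(inherits(basis, "zernike_basis"))
  if (length(coeffs) != nrow(basis$terms))
    stop("coefficient vector length ", length(coeffs),
         " does not match the ", nrow(basis$terms), "-term basis",
         call. = FALSE)
  d <- basis$grid_shape
  matrix(matrix(basis$maps, prod(d)) %*% coeffs, d[1], d[2])
}

#' Aberrated pupil function
#'
#' Assembles the complex pupil C(k) = c(k) * exp(i * sum_i c_i Z_i(k)):
#' a non-negative amplitude map (the CTF modulus, updated as a whole
#' during pupil recovery) and a Zernike-parameterized phase. With all
#' coefficients zero and the ideal binary CTF amplitude this reduces to
#' the diffraction-limited pupil.
#'
#' @param amplitude non-negative amplitude matrix on the pupil grid.
#' @param basis a [zernike_basis] on the same grid.
#' @param coeffs Zernike phase coefficients, radians.
#' @return an object of class `fpm_pupil`: amplitude, coefficients,
#'   basis, phase map, support mask, and the complex `values`.
#' @export
build_pupil <- function(amplitude, basis, coeffs = NULL) {
  stopifnot(inherits(basis, "zernike_basis"))
  if (is.null(coeffs)) coeffs <- numeric(nrow(basis$terms))
  if (!all(dim(amplitude) == basis$grid_shape))
    stop("amplitude grid does not match the basis grid", call. = FALSE)
  if (any(amplitude < 0))
    stop("pupil amplitude must be non-negative", call. = FALSE)
  phase <- zernike_phase(basis, coeffs)
  structure(list(amplitude = amplitude, zernike_coeffs = coeffs,
                 basis = basis, phase = phase, support = basis$support,
                 values = amplitude * exp(1i * phase)),
            class = "fpm_pupil")
}

#' @export
print.fpm_pupil <- function(x, ...) {
  cat(sprintf("<fpm_pupil> %d x %d, %d-pixel support\n",
              nrow(x$amplitude), ncol(x$amplitude), sum(x$support)))
  nz <- which(abs(x$zernike_coeffs) > 1e-12)
  if (length(nz)) {
    tt <- x$basis$terms[nz, , drop = FALSE]
    cat("  Zernike phase terms (rad):\n")
    for (i in seq_along(nz))
      cat(sprintf("    (n=%d, m=%+d): %+.4f\n", tt$n[i], tt$m[i],
                  x$zernike_coeffs[nz[i]]))
  } else cat("  no phase aberration\n")
  invisible(x)
}

#' Defocus distance to Zernike defocus coefficient
#'
#' Converts a defocus distance z (micrometres) into the coefficient of
#' the unit-normalized defocus polynomial 2 rho^2 - 1 over the pupil disk
#' (rho = |k| lambda / NA), in radians. Two pupil-phase models are
#' offered: `"paraxial"` uses -k0 z (NA rho)^2 / 2, whose least-squares
#' projection onto 2 rho^2 - 1 is exactly -k0 z NA^2 / 4 (linear in z);
#' `"exact"` projects the full defocus phase
#' k0 z (sqrt(1 - (NA rho)^2) - 1), which at NA = 0.1 differs from the
#' paraxial value by well under 1 percent. For a 50 um defocus at
#' NA = 0.1, lambda = 532 nm, the coefficient is about -1.48 rad.
#'
#' @param z defocus distance, micrometres (sign flips with z).
#' @param system an [fpm_system] (wavelength and NA are used).
#' @param model `"paraxial"` or `"exact"`.
#' @param n_rho number of radial quadrature points for the projection.
#' @return defocus coefficient in radians (unit 2 rho^2 - 1 convention).
#' @export
defocus_to_zernike <- function(z, system, model = c("paraxial", "exact"),
                               n_rho = 2048L) {
  model <- match.arg(model)
  if (z == 0) return(0)
  # midpoint quadrature of the radial least-squares projection
  rho <- (seq_len(n_rho) - 0.5) / n_rho
  w <- rho / n_rho                      # disk measure rho d rho
  phase <- if (model == "paraxial") {
    -system$k0 * z * (system$na * rho)^2 / 2
  } else {
    system$k0 * z * (sqrt(1 - (system$na * rho)^2) - 1)
  }
  basis <- 2 * rho^2 - 1
  sum(phase * basis * w) / sum(basis^2 * w)
}
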