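# Shared fixtures and independent oracles, built in code at test time.

# Small wide-aperture system: 8x8 high-res grid, 4x4 pupil window, so
# brute-force oracles stay cheap.
tiny_system <- function(hires = 8L, u = 2L, na = 0.4) {
  fpm_system(wavelength = 0.532, na = na, pixel_size_obj = 0.3,
             hires_shape = hires, upsampling = u)
}

# Brute-force centered unitary DFT (double loop) — the independent
# oracle for every FFT-based operation.
dftc_oracle <- function(x, inverse = FALSE) {
  n1 <- nrow(x); n2 <- ncol(x)
  c1 <- floor(n1 / 2) + 1; c2 <- floor(n2 / 2) + 1
  sgn <- if (inverse) 2i else -2i
  out <- matrix(0 + 0i, n1, n2)
  for (p in seq_len(n1)) for (q in seq_len(n2)) {
    acc <- 0 + 0i
    for (r in seq_len(n1)) for (cc in seq_len(n2))
      acc <- acc + x[r, cc] *
        exp(sgn * pi * ((p - c1) * (r - c1) / n1 +
                          (q - c2) * (cc - c2) / n2))
    out[p, q] <- acc
  }
  out / sqrt(n1 * n2)
}

# Random complex matrix with reproducible entries.
rand_cplx <- function(n1, n2 = n1, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n1 * n2, sd = sd),
                 imaginary = rnorm(n1 * n2, sd = sd)), n1, n2)
}

# A small defocused benchmark reused by several tests (32x32, 5x5 LEDs,
# wide pitch for aperture span).
small_bench <- function(z = 0, seed = 1, leds_shape = c(5L, 5L)) {
  sys <- fpm_system(hires_shape = 32L, upsampling = 2L)
  make_benchmark_case(z = z,
                      spec = phantom_spec(32L, seed = seed),
                      leds = led_array(leds_shape, pitch = 10),
                      system = sys, seed = seed)
}

# Loss of the IWF forward chain as a plain function of the parameter
# blocks — used by finite-difference gradient oracles.
iwf_loss_fn <- function(o_r, o_i, camp, coeffs, basis, delta, windows,
                        y, sqrt_y) {
  theta <- zernike_phase(basis, coeffs)
  fpmflow:::iwf_batch_grad(o_r, o_i, camp, theta, basis, delta, windows,
                           y, sqrt_y, want_grad = FALSE)$loss
}

# Precomputed window index sets for a system + wave-vector matrix.
iwf_windows <- function(system, wavevectors) {
  lapply(seq_len(nrow(wavevectors)), function(i) {
    q <- fpmflow:::quantize_shift(wavevectors[i, ], system$dk)
    fpmflow:::window_ranges(system$hires_shape, system$lores_shape,
                            q$offset)
  })
}

# Shared tiny problem for the gradient oracles: 8x8 object, 4x4 pupil
# windows, 3 LEDs with nonzero shifts.
iwf_toy <- function(seed = 3) {
  sys <- tiny_system()
  basis <- zernike_basis(sys, zernike_terms(2))
  set.seed(seed)
  M <- sys$hires_shape[1]; m <- sys$lores_shape[1]
  kns <- rbind(c(0, 0), c(sys$dk, 0), c(-sys$dk, sys$dk))
  list(sys = sys, basis = basis,
       o_r = matrix(rnorm(M * M, sd = 0.5), M),
       o_i = matrix(rnorm(M * M, sd = 0.5), M),
       camp = make_ctf(sys) *
         matrix(runif(m * m, 0.5, 1), m),
       coeffs = rnorm(nrow(basis$terms), sd = 0.3),
       windows = iwf_windows(sys, kns),
       y = lapply(1:3, function(i) matrix(runif(m * m, 0.1, 1), m)))
}

# Independent windowed-SSIM oracle: explicit loop over 7x7 windows.
ssim_window_oracle <- function(x, y, c1 = 1e-4, c2 = 9e-4, w = 7L) {
  vals <- c()
  for (i in seq_len(nrow(x) - w + 1)) for (j in seq_len(ncol(x) - w + 1)) {
    a <- x[i:(i + w - 1), j:(j + w - 1)]
    b <- y[i:(i + w - 1), j:(j + w - 1)]
    mu1 <- mean(a); mu2 <- mean(b)
    v1 <- stats::var(c(a)); v2 <- stats::var(c(b))
    cv <- stats::cov(c(a), c(b))
    vals <- c(vals, ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
                ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2)))
  }
  mean(vals)
}

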