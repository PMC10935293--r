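# Independent oracle: a self-contained alternating-projection FPM
# reconstruction written directly from the update equations, sharing no
# code with the package implementation beyond base R's fft.
oracle_ap_sweep <- function(S, pupilv, wavevectors, images, dk) {
  M <- dim(S); m <- dim(pupilv)
  shift2 <- function(x, s1, s2) {
    # centered-layout unitary transforms, written independently
    n <- nrow(x)
    idx1 <- ((seq_len(n) - 1 + s1) %% n) + 1
    idx2 <- ((seq_len(n) - 1 + s2) %% n) + 1
    x[idx1, idx2]
  }
  u_fft <- function(x, inv = FALSE) {
    n1 <- nrow(x); n2 <- ncol(x)
    sh <- function(z) shift2(z, floor(n1 / 2), floor(n2 / 2))
    ish <- function(z) shift2(z, -floor(n1 / 2), -floor(n2 / 2))
    ish(stats::fft(sh(x), inverse = inv)) / sqrt(n1 * n2)
  }
  cM <- floor(M / 2) + 1; cm <- floor(m / 2) + 1
  for (i in seq_len(nrow(wavevectors))) {
    s <- round(wavevectors[i, ] / dk)
    rows <- cM[1] - s[2] - cm[1] + seq_len(m[1])
    cols <- cM[2] - s[1] - cm[2] + seq_len(m[2])
    phi <- S[rows, cols] * pupilv
    g <- u_fft(phi, inv = TRUE)
    g2 <- sqrt(images[, , i]) * exp(1i * Arg(g))
    phi2 <- u_fft(g2)
    upd <- Mod(pupilv) > 1e-12
    patch <- S[rows, cols]
    patch[upd] <- phi2[upd] / pupilv[upd]
    S[rows, cols] <- patch
  }
  S
}

test_that("estimate_lowres matches the forward model and the DFT oracle", {
  sys <- tiny_system()
  basis <- zernike_basis(sys, zernike_terms(2))
  pup <- build_pupil(make_ctf(sys), basis, rnorm(6, sd = 0.3))
  # zero spectrum gives a zero field
  z <- estimate_lowres(matrix(0 + 0i, 8, 8), pup, c(0, 0), sys)
  expect_equal(max(Mod(z)), 0)
  # all-pass pupil at u = 1, k = 0 returns the object field itself
  sys1 <- fpm_system(wavelength = 0.532, na = 0.4, pixel_size_obj = 0.3,
                     hires_shape = 8L, upsampling = 1L)
  obj <- rand_cplx(8, seed = 5)
  allpass <- matrix(1 + 0i, 8, 8)
  expect_equal(estimate_lowres(fft2c(obj), allpass, c(0, 0), sys1), obj,
               tolerance = 1e-10)
  # against the brute-force DFT oracle on 8x8
  S <- fft2c(rand_cplx(8, seed = 6))
  kn <- c(-sys$dk, sys$dk)
  g <- estimate_lowres(S, pup, kn, sys)
  win <- fpmflow:::spectrum_window(S, kn, sys$dk, sys$lores_shape)
  expect_lt(max(Mod(g - dftc_oracle(win$values * pup$values,
                                    inverse = TRUE))), 1e-8)
})

test_that("spectrum_update is a fixed point on consistent data", {
  bench <- small_bench(z = 25)
  sys <- bench$system
  S <- fft2c(bench$truth$values)
  S1 <- S
  for (i in seq_len(dim(bench$stack$images)[3]))
    S1 <- spectrum_update(S1, bench$pupil, bench$stack$wavevectors[i, ],
                          bench$stack$images[, , i], sys)
  expect_lt(max(Mod(S1 - S)), 1e-10)
  # measured = 0 zeroes the patch amplitude inside the support
  S2 <- spectrum_update(S, bench$pupil, c(0, 0),
                        matrix(0, sys$lores_shape[1], sys$lores_shape[2]),
                        sys)
  win <- fpmflow:::spectrum_window(S2, c(0, 0), sys$dk, sys$lores_shape)
  expect_lt(max(Mod(win$values[bench$pupil$support])), 1e-12)
  expect_error(spectrum_update(S, bench$pupil, c(0, 0),
                               matrix(-1, sys$lores_shape[1],
                                      sys$lores_shape[2]), sys),
               "non-negative")
})

test_that("one sweep agrees with an independent alternating-projection oracle", {
  bench <- small_bench(z = 50, seed = 2)
  sys <- bench$system
  init <- fft2c(bench$truth$values) * 0.7 + 0.1   # a deliberately off start
  S_pkg <- init
  for (i in seq_len(dim(bench$stack$images)[3]))
    S_pkg <- spectrum_update(S_pkg, bench$pupil,
                             bench$stack$wavevectors[i, ],
                             bench$stack$images[, , i], sys)
  S_orc <- oracle_ap_sweep(init, bench$pupil$values,
                           bench$stack$wavevectors, bench$stack$images,
                           sys$dk)
  expect_lt(max(Mod(S_pkg - S_orc)), 1e-8)
  # and the sweep reduces the intensity misfit
  misfit <- function(S) {
    tot <- 0
    for (i in seq_len(dim(bench$stack$images)[3])) {
      g <- estimate_lowres(S, bench$pupil, bench$stack$wavevectors[i, ],
                           sys)
      tot <- tot + sum((Mod(g)^2 - bench$stack$images[, , i])^2)
    }
    tot
  }
  expect_lt(misfit(S_pkg), misfit(init))
})

test_that("classic reconstruction improves on the raw central image", {
  bench <- small_bench(z = 0, seed = 1)
  rec <- reconstruct_classic(bench$stack, n_iters = 20)
  ev <- evaluate_reconstruction(bench$truth, rec$object)
  ctr <- which.min(rowSums(bench$stack$wavevectors^2))
  raw <- Mod(upsample_fourier(sqrt(bench$stack$images[, , ctr]),
                              bench$system$upsampling))
  raw_psnr <- psnr(normalize01(Mod(bench$truth$values)), normalize01(raw))
  expect_gt(ev$psnr_amp, raw_psnr)
  # no better raw image exists anywhere in the stack
  best_raw <- max(vapply(seq_len(dim(bench$stack$images)[3]), function(i) {
    up <- Mod(upsample_fourier(sqrt(bench$stack$images[, , i]),
                               bench$system$upsampling))
    psnr(normalize01(Mod(bench$truth$values)), normalize01(up))
  }, numeric(1)))
  expect_gt(ev$psnr_amp, best_raw)
})

test_that("supplying the true aberrated pupil beats assuming the ideal CTF", {
  bench <- small_bench(z = 50, seed = 1)
  rec_true <- reconstruct_classic(bench$stack, pupil = bench$pupil,
                                  n_iters = 25)
  rec_ideal <- reconstruct_classic(bench$stack, n_iters = 25)
  pt <- evaluate_reconstruction(bench$truth, rec_true$object)$psnr_amp
  pi_ <- evaluate_reconstruction(bench$truth, rec_ideal$object)$psnr_amp
  expect_gt(pt, pi_)
})

test_that("n_iters = 0 returns the initialization and misfit is monotone", {
  bench <- small_bench(z = 0, seed = 2)
  rec0 <- reconstruct_classic(bench$stack, n_iters = 0)
  expect_equal(rec0$iterations, 0L)
  expect_equal(nrow(rec0$trace), 0L)
  # the returned object is the Fourier-upsampled central image
  ctr <- which.min(rowSums(bench$stack$wavevectors^2))
  up <- upsample_fourier(sqrt(bench$stack$images[, , ctr]),
                         bench$system$upsampling)
  expect_equal(rec0$object$values, up, tolerance = 1e-10)
  rec <- reconstruct_classic(bench$stack, n_iters = 10, tol = 0)
  dm <- diff(rec$trace$misfit)
  expect_true(all(dm <= 1e-6 * abs(rec$trace$misfit[-nrow(rec$trace)])))
})
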