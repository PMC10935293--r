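test_that("luda_forward equals the native shifted-spectrum pupil product", {
  sys <- tiny_system()
  basis <- zernike_basis(sys, zernike_terms(2))
  set.seed(9)
  obj <- rand_cplx(8, seed = 9, sd = 0.5)
  cf <- rnorm(nrow(basis$terms), sd = 0.3)
  camp <- make_ctf(sys)
  par <- iwf_params(Re(obj), Im(obj), camp, cf, basis)
  kn <- c(sys$dk, -sys$dk)
  phi <- luda_forward(par, kn, sys)
  # native complex product computed independently
  W <- fpmflow:::spectrum_window(fft2c(obj), kn, sys$dk,
                                 sys$lores_shape)$values
  C <- camp * exp(1i * zernike_phase(basis, cf))
  expect_lt(max(Mod(phi - W * C)), 1e-12)
  # identity pupil, axial LED: phi_l is the central spectrum window
  par1 <- iwf_params(Re(obj), Im(obj), matrix(1, 4, 4),
                     numeric(nrow(basis$terms)), basis)
  phi0 <- luda_forward(par1, c(0, 0), sys)
  W0 <- fpmflow:::spectrum_window(fft2c(obj), c(0, 0), sys$dk,
                                  sys$lores_shape)$values
  expect_lt(max(Mod(phi0 - W0)), 1e-12)
  # a point object has a flat spectrum: phi_l is the pupil scaled by it
  dl <- matrix(0, 8, 8)
  ctr <- floor(8 / 2) + 1
  dl[ctr, ctr] <- 1
  pard <- iwf_params(dl, dl * 0, camp, cf, basis)
  phid <- luda_forward(pard, c(0, 0), sys)
  expect_lt(max(Mod(phid - (1 / 8) * C)), 1e-12)  # spectrum value 1/sqrt(64)
})

test_that("wfm_update applies -delta/4 of the intensity-misfit gradient", {
  set.seed(10)
  phi <- rand_cplx(4, seed = 10)
  y <- matrix(runif(16, 0.1, 1), 4)
  expect_equal(wfm_update(phi, y, 0), phi)
  # zero gradient at the intensity-consistent point
  a <- ifft2c(phi)
  y_fit <- Mod(a)^2
  expect_lt(max(Mod(wfm_update(phi, y_fit, 0.7) - phi)), 1e-12)
  # central finite differences of f(phi) = sum(( |F^-1 phi|^2 - y )^2)
  f <- function(p) sum((Mod(ifft2c(p))^2 - y)^2)
  h <- 1e-6
  delta <- 0.7
  corr <- wfm_update(phi, y, delta) - phi
  for (idx in c(1L, 6L, 11L, 16L)) {
    pr <- phi; pr[idx] <- pr[idx] + h
    pl <- phi; pl[idx] <- pl[idx] - h
    gr <- (f(pr) - f(pl)) / (2 * h)
    pi_ <- phi; pi_[idx] <- pi_[idx] + 1i * h
    pm <- phi; pm[idx] <- pm[idx] - 1i * h
    gi <- (f(pi_) - f(pm)) / (2 * h)
    # correction = -delta/4 * (df/dRe + i df/dIm)
    expect_equal(Re(corr[idx]), -delta / 4 * gr, tolerance = 1e-5)
    expect_equal(Im(corr[idx]), -delta / 4 * gi, tolerance = 1e-5)
  }
  expect_error(wfm_update(phi, matrix(1, 3, 3), 1), "share a grid")
})

test_that("wfn_constraint replaces the modulus and keeps the phase", {
  set.seed(11)
  phi_m <- rand_cplx(8, seed = 11)
  I <- matrix(runif(64, 0, 1), 8)
  phi_h <- wfn_constraint(phi_m, I)
  expect_equal(Mod(ifft2c(phi_h))^2, I, tolerance = 1e-10)
  # already-satisfied constraint is a fixed point
  b <- ifft2c(phi_m)
  I_fit <- Mod(b)^2
  expect_lt(max(Mod(wfn_constraint(phi_m, I_fit) - phi_m)), 1e-10)
  # zero intensity gives the zero spectrum
  expect_equal(max(Mod(wfn_constraint(phi_m, I * 0))), 0)
  expect_error(wfn_constraint(phi_m, I - 2), "non-negative")
})

test_that("the spectral loss matches independent arithmetic", {
  expect_equal(iwf_loss(rand_cplx(4, seed = 1), rand_cplx(4, seed = 1)), 0)
  phi <- rand_cplx(4, seed = 12)
  cst <- 0.3 - 0.4i
  expect_equal(iwf_loss(phi + cst, phi), Mod(cst)^2, tolerance = 1e-12)
  a <- rand_cplx(4, seed = 13); b <- rand_cplx(4, seed = 14)
  hand <- sum((Re(a - b))^2 + (Im(a - b))^2) / 16
  expect_equal(iwf_loss(a, b), hand, tolerance = 1e-12)
  # batch form averages over LEDs
  expect_equal(iwf_loss(list(a, a), list(b, b)), hand, tolerance = 1e-12)
})

test_that("Wirtinger adjoint gradients match central finite differences", {
  toy <- iwf_toy()
  sqrt_y <- lapply(toy$y, sqrt)
  for (detach in c(FALSE, TRUE)) {
    theta <- zernike_phase(toy$basis, toy$coeffs)
    g <- fpmflow:::iwf_batch_grad(toy$o_r, toy$o_i, toy$camp, theta,
                                  toy$basis, 0.7, toy$windows, toy$y,
                                  sqrt_y, detach_target = detach)
    h <- 1e-6
    fd_check <- function(block, analytic) {
      set.seed(99)
      for (t in 1:5) {
        i <- sample(length(analytic), 1)
        args <- list(o_r = toy$o_r, o_i = toy$o_i, camp = toy$camp,
                     coeffs = toy$coeffs)
        pr <- args; pr[[block]][i] <- pr[[block]][i] + h
        pl <- args; pl[[block]][i] <- pl[[block]][i] - h
        num <- (do.call(iwf_loss_fn, c(pr, list(basis = toy$basis,
                   delta = 0.7, windows = toy$windows, y = toy$y,
                   sqrt_y = sqrt_y))) -
                do.call(iwf_loss_fn, c(pl, list(basis = toy$basis,
                   delta = 0.7, windows = toy$windows, y = toy$y,
                   sqrt_y = sqrt_y)))) / (2 * h)
        expect_equal(analytic[i], num, tolerance = 1e-4)
      }
    }
    fd_check("o_r", g$g_sample_real)
    fd_check("o_i", g$g_sample_imag)
    fd_check("camp", g$g_ctf_amplitude)
    fd_check("coeffs", g$g_zernike)
  }
})

test_that("noiseless truth is a fixed point of training", {
  bench <- small_bench(z = 50, seed = 1)
  sys <- bench$system
  scale <- mean(bench$stack$images)
  o <- bench$truth$values / sqrt(scale)
  basis <- bench$pupil$basis
  init <- iwf_params(Re(o), Im(o), make_ctf(sys),
                     bench$pupil$zernike_coeffs, basis)
  # stationarity is a property of the plain gradient-descent rule:
  # adaptive moments rescale vanishing gradients up to the lr scale
  cfg <- iwf_config(epochs = 5L, zernike_n_max = 4L,
                    au_schedule = c("sample", "pupil"),
                    optimizer = "sgd")
  fit <- train_inn_iwf(bench$stack, init = init, config = cfg)
  expect_lt(max(fit$loss_trace), 1e-15)
  expect_lt(max(abs(fit$params$zernike_coeffs -
                      bench$pupil$zernike_coeffs)), 1e-8)
  expect_lt(max(Mod(fit$params$sample_real + 1i * fit$params$sample_imag
                    - o)), 1e-8)
})

test_that("alternating updates touch only the active parameter block", {
  bench <- small_bench(z = 25, seed = 2)
  # sample-only epochs: pupil block bit-identical
  fs <- train_inn_iwf(bench$stack,
                      config = iwf_config(epochs = 3L,
                                          au_schedule = "sample"))
  expect_identical(fs$params$zernike_coeffs,
                   numeric(length(fs$params$zernike_coeffs)))
  expect_identical(fs$params$ctf_amplitude, make_ctf(bench$system))
  # pupil-only epochs: sample block bit-identical to its initialization
  init0 <- train_inn_iwf(bench$stack,
                         config = iwf_config(epochs = 1L,
                                             au_schedule = "pupil"))
  scale <- mean(bench$stack$images)
  ctr <- which.min(rowSums(bench$stack$wavevectors^2))
  M <- bench$system$hires_shape
  big <- matrix(0 + 0i, M[1], M[2])
  w0 <- fpmflow:::window_ranges(M, bench$system$lores_shape)
  big[w0$rows, w0$cols] <- fft2c(sqrt(bench$stack$images[, , ctr] / scale))
  o0 <- ifft2c(big)
  expect_identical(init0$params$sample_real, Re(o0))
  expect_identical(init0$params$sample_imag, Im(o0))
  expect_false(identical(init0$params$zernike_coeffs,
                         numeric(length(init0$params$zernike_coeffs))))
})

test_that("zero learning rates leave all parameters unchanged", {
  bench <- small_bench(z = 25, seed = 1)
  fit <- train_inn_iwf(bench$stack,
                       config = iwf_config(epochs = 4L, lr_sample = 0,
                                           lr_pupil = 0,
                                           sample_update = "gradient",
                                           optimizer = "sgd"))
  expect_identical(fit$params$zernike_coeffs,
                   numeric(length(fit$params$zernike_coeffs)))
  # projection mode with relaxation 0 is likewise inert
  fit0 <- train_inn_iwf(bench$stack,
                        config = iwf_config(epochs = 4L, lr_sample = 0,
                                            lr_pupil = 0))
  expect_equal(fit$params$sample_real, fit0$params$sample_real)
})

test_that("the loss trace is non-increasing for small gradient steps", {
  bench <- small_bench(z = 25, seed = 1)
  fit <- train_inn_iwf(bench$stack,
                       config = iwf_config(epochs = 20L,
                                           sample_update = "gradient",
                                           optimizer = "sgd",
                                           lr_sample = 0.05,
                                           lr_pupil = 0.5))
  lt <- fit$loss_trace
  expect_true(all(diff(lt) <= 1e-6 * lt[-length(lt)]))
})

test_that("training diverging to non-finite loss is reported", {
  bench <- small_bench(z = 25, seed = 1)
  expect_error(
    train_inn_iwf(bench$stack,
                  config = iwf_config(epochs = 40L,
                                      sample_update = "gradient",
                                      optimizer = "sgd",
                                      au_schedule = "sample",
                                      lr_sample = 1e10)),
    "diverged")
})
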