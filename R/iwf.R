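# Aberration-correcting FPM reconstruction by Wirtinger-Flow gradient
# descent ("IWF" engine).
#
# The object is carried as learnable real/imaginary high-resolution maps
# and the pupil as a learnable non-negative CTF amplitude plus Zernike
# phase coefficients. For each LED the forward chain is
#
#   phi_l = O(k -+ k_n) . C(k)                    (pupil-window spectrum)
#   a     = F^-1 phi_l
#   phi_m = phi_l - delta * F{ (|a|^2 - y) . a }  (one WF intensity step)
#   f     = Arg(F^-1 phi_m)
#   phi_h = F{ sqrt(y) . exp(i f) }               (intensity constraint)
#
# and the scalar objective is the mean over pixels and LEDs of
# |phi_h - phi_l|^2: the corrected-and-constrained spectrum should agree
# with the spectrum the current sample/pupil estimates predict. Gradients
# with respect to every parameter block are hand-derived Wirtinger
# adjoints of this chain (unitary transforms make every adjoint an
# inverse transform); they are validated against central finite
# differences in the test suite. Training alternates epochs that update
# only the sample with epochs that update only the pupil (the
# alternating-update schedule), since the two blocks need very different
# step sizes.

#' Parameter block for the Wirtinger-Flow reconstruction
#'
#' @param sample_real,sample_imag real and imaginary parts of the
#'   high-resolution object estimate (matrices).
#' @param ctf_amplitude non-negative CTF amplitude map, low-res grid.
#' @param zernike_coeffs Zernike phase coefficients, radians.
#' @param basis a [zernike_basis] on the low-res grid.
#' @param delta Wirtinger gradient step inside the WFM correction
#'   (dimensionless; intensities are pre-normalized to unit mean).
#' @return an object of class `iwf_params`.
#' @export
iwf_params <- function(sample_real, sample_imag, ctf_amplitude,
                       zernike_coeffs, basis, delta = 1) {
  stopifnot(all(dim(sample_real) == dim(sample_imag)),
            inherits(basis, "zernike_basis"),
            all(dim(ctf_amplitude) == basis$grid_shape),
            length(zernike_coeffs) == nrow(basis$terms),
            delta >= 0, all(is.finite(sample_real)),
            all(is.finite(sample_imag)), all(ctf_amplitude >= 0))
  structure(list(sample_real = sample_real, sample_imag = sample_imag,
                 ctf_amplitude = ctf_amplitude,
                 zernike_coeffs = zernike_coeffs, basis = basis,
                 delta = delta),
            class = "iwf_params")
}

# Current complex pupil of a parameter block.
#' @keywords internal
iwf_pupil_values <- function(params) {
  params$ctf_amplitude * exp(1i * zernike_phase(params$basis,
                                                params$zernike_coeffs))
}

#' Per-LED forward unit: pupil-window spectrum
#'
#' Computes phi_l = O(k shifted by k_n) . C(k) on the pupil window, the
#' spectrum "before update". The complex product is evaluated through
#' its real/imaginary expansion
#' (Or.Cr - Oi.Ci) + i (Or.Ci + Oi.Cr), which is identical to the native
#' complex product.
#'
#' @param params an [iwf_params].
#' @param k_n illumination wave vector, cycles/um.
#' @param system an [fpm_system].
#' @return complex matrix phi_l on the low-resolution grid.
#' @export
luda_forward <- function(params, k_n, system) {
  S <- fft2c(params$sample_real + 1i * params$sample_imag)
  W <- spectrum_window(S, k_n, system$dk, system$lores_shape)$values
  C <- iwf_pupil_values(params)
  Or <- Re(W); Oi <- Im(W); Cr <- Re(C); Ci <- Im(C)
  (Or * Cr - Oi * Ci) + 1i * (Or * Ci + Oi * Cr)
}

#' Wirtinger-Flow spectrum correction (WFM)
#'
#' One gradient step on the intensity misfit || |F^-1 phi|^2 - y ||^2
#' taken in the spectrum domain:
#' phi_m = phi_l - delta * F{ (|a|^2 - y) . a } with a = F^-1 phi_l.
#' Because the transforms are unitary, the applied correction equals
#' -delta/4 times the (real/imaginary) gradient of the misfit.
#'
#' @param phi_l complex spectrum matrix.
#' @param y measured intensity on the same grid (non-negative).
#' @param delta step size (>= 0).
#' @return complex matrix phi_m.
#' @export
wfm_update <- function(phi_l, y, delta) {
  if (!all(dim(phi_l) == dim(y)))
    stop("phi_l and y must share a grid", call. = FALSE)
  a <- ifft2c(phi_l)
  phi_l - delta * fft2c((Mod(a)^2 - y) * a)
}

#' Intensity-constrained phase module (WFN)
#'
#' Keeps the phase of F^-1(phi_m) and replaces its modulus by the square
#' root of the measured intensity (upsampled to the phi grid when the
#' two differ): phi_h = F{ sqrt(I) . exp(i Arg(F^-1 phi_m)) }.
#'
#' @param phi_m complex spectrum matrix.
#' @param measured_intensity non-negative intensity map; if smaller than
#'   the phi grid it is upsampled by [upsample_intensity()].
#' @param upsample_method method passed to [upsample_intensity()].
#' @return complex matrix phi_h with |F^-1 phi_h| = sqrt(I) pointwise.
#' @export
wfn_constraint <- function(phi_m, measured_intensity,
                           upsample_method = "fourier") {
  if (any(measured_intensity < 0))
    stop("measured intensities must be non-negative", call. = FALSE)
  d <- dim(phi_m)
  if (!all(dim(measured_intensity) == d)) {
    fac <- d[1] / nrow(measured_intensity)
    if (fac != round(fac) || d[2] / ncol(measured_intensity) != fac)
      stop("measured intensity grid is not an integer factor of the phi grid",
           call. = FALSE)
    measured_intensity <- upsample_intensity(measured_intensity, fac,
                                             upsample_method)
  }
  f <- Arg(ifft2c(phi_m))
  fft2c(sqrt(measured_intensity) * exp(1i * f))
}

#' Upsample an intensity image
#'
#' Fourier method: zero-pad the spectrum of sqrt(I), inverse-transform,
#' rescale to preserve amplitude levels, and re-square (guaranteeing a
#' non-negative result); alternatives are nearest-neighbour and bilinear
#' interpolation of the intensities.
#'
#' @param I non-negative intensity matrix.
#' @param factor integer upsampling factor.
#' @param method `"fourier"`, `"nearest"`, or `"bilinear"`.
#' @return non-negative matrix `factor` times larger in each dimension.
#' @export
upsample_intensity <- function(I, factor,
                               method = c("fourier", "nearest",
                                          "bilinear")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (factor == 1L) return(I)
  if (method == "fourier") {
    amp <- Mod(upsample_fourier(sqrt(I), factor)) * factor
    return(amp^2)
  }
  if (method == "nearest")
    return(I[rep(seq_len(nrow(I)), each = factor),
             rep(seq_len(ncol(I)), each = factor)])
  # bilinear on the pixel-center grid
  n1 <- nrow(I) * factor; n2 <- ncol(I) * factor
  src_r <- pmin(pmax(((seq_len(n1) - 0.5) / factor) + 0.5, 1), nrow(I))
  src_c <- pmin(pmax(((seq_len(n2) - 0.5) / factor) + 0.5, 1), ncol(I))
  r0 <- pmin(floor(src_r), nrow(I) - 1L); c0 <- pmin(floor(src_c),
                                                     ncol(I) - 1L)
  wr <- src_r - r0; wc <- src_c - c0
  (1 - wr) %o% (1 - wc) * I[r0, c0] + (1 - wr) %o% wc * I[r0, c0 + 1L] +
    wr %o% (1 - wc) * I[r0 + 1L, c0] + wr %o% wc * I[r0 + 1L, c0 + 1L]
}

#' Spectral self-consistency loss
#'
#' Mean over pixels (and, for lists, over LEDs) of |phi_h - phi_l|^2:
#' zero exactly when the constrained spectra agree with the predicted
#' ones.
#'
#' @param phi_h,phi_l complex matrices, or lists of matrices (one per
#'   LED).
#' @return non-negative scalar.
#' @export
iwf_loss <- function(phi_h, phi_l) {
  if (is.list(phi_h)) {
    stopifnot(length(phi_h) == length(phi_l))
    return(mean(vapply(seq_along(phi_h),
                       function(i) mean(Mod(phi_h[[i]] - phi_l[[i]])^2),
                       numeric(1))))
  }
  mean(Mod(phi_h - phi_l)^2)
}

# ---------------------------------------------------------------------------
# Training: forward + hand-derived Wirtinger adjoints
# ---------------------------------------------------------------------------

# Adam optimizer state for one parameter block. With an exactly zero
# gradient the step is exactly zero, so a noiseless fixed point stays
# fixed.
#' @keywords internal
adam_state <- function() list(m = 0, v = 0, t = 0L)

#' @keywords internal
adam_step <- function(state, g, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$step <- lr * mhat / (sqrt(vhat) + eps)
  state
}

# Forward pass and gradient accumulation for the whole LED batch.
# Returns loss and gradients for (sample_real, sample_imag,
# ctf_amplitude, zernike_coeffs). `windows` is a list of precomputed
# row/col index pairs per LED; y / sqrt_y are normalized intensities.
#' @keywords internal
iwf_batch_grad <- function(o_r, o_i, camp, theta, basis, delta, windows,
                           y, sqrt_y, detach_target = FALSE,
                           want_grad = TRUE, eps_b = 1e-12) {
  M <- dim(o_r); m <- dim(camp); n_led <- length(windows)
  P <- prod(m)
  S <- fft2c(o_r + 1i * o_i)
  C <- camp * exp(1i * theta)
  g_S <- if (want_grad) matrix(0 + 0i, M[1], M[2]) else NULL
  g_camp <- if (want_grad) matrix(0, m[1], m[2]) else NULL
  g_theta <- if (want_grad) matrix(0, m[1], m[2]) else NULL
  loss <- 0
  for (n in seq_len(n_led)) {
    w <- windows[[n]]
    W <- S[w$rows, w$cols, drop = FALSE]
    phi_l <- W * C
    a <- ifft2c(phi_l)
    e <- Mod(a)^2 - y[[n]]
    phi_m <- phi_l - delta * fft2c(e * a)
    b <- ifft2c(phi_m)
    absb <- Mod(b)
    f <- ifelse(absb > eps_b, b / absb, 1 + 0i)
    phi_h <- fft2c(sqrt_y[[n]] * f)
    d <- phi_h - phi_l
    loss <- loss + mean(Mod(d)^2)
    if (!want_grad) next
    gd <- d / (P * n_led)
    g_phi_l <- -gd
    if (!detach_target) {
      g_sf <- ifft2c(gd)                       # adjoint of fft2c
      g_f <- g_sf * sqrt_y[[n]]
      g_b <- (g_f - Conj(g_f) * f^2) / (2 * absb)
      g_b[absb <= eps_b] <- 0 + 0i
      g_phi_m <- fft2c(g_b)                    # adjoint of ifft2c
      g_phi_l <- g_phi_l + g_phi_m
      g_t <- -delta * ifft2c(g_phi_m)
      g_a <- g_t * e + (2 * Re(Conj(g_t) * a)) * a
      g_phi_l <- g_phi_l + fft2c(g_a)
    }
    g_S[w$rows, w$cols] <- g_S[w$rows, w$cols] + g_phi_l * Conj(C)
    g_C <- g_phi_l * Conj(W)
    g_camp <- g_camp + 2 * Re(Conj(g_C) * exp(1i * theta))
    g_theta <- g_theta - 2 * Im(Conj(g_C) * C)
  }
  loss <- loss / n_led
  out <- list(loss = loss)
  if (want_grad) {
    g_O <- ifft2c(g_S)
    out$g_sample_real <- 2 * Re(g_O)
    out$g_sample_imag <- 2 * Im(g_O)
    out$g_ctf_amplitude <- g_camp
    d3 <- dim(basis$maps)
    out$g_zernike <- as.numeric(
      crossprod(matrix(basis$maps, d3[1] * d3[2], d3[3]),
                as.numeric(g_theta)))
  }
  out
}

#' Alternating-update schedule
#'
#' Builds the epoch-by-epoch alternation pattern: `rounds` repetitions
#' of a sample block followed by a pupil block, then a final sample
#' block that re-converges the object under the recovered pupil.
#'
#' @param rounds number of sample/pupil rounds.
#' @param sample_epochs epochs per sample block.
#' @param pupil_epochs epochs per pupil block.
#' @param final_sample epochs of the trailing sample block.
#' @return character vector of `"sample"` / `"pupil"` phase labels.
#' @export
iwf_au_schedule <- function(rounds = 6L, sample_epochs = 10L,
                            pupil_epochs = 30L, final_sample = 10L) {
  c(rep(c(rep("sample", sample_epochs), rep("pupil", pupil_epochs)),
        rounds),
    rep("sample", final_sample))
}

#' Training configuration for the IWF engine
#'
#' Defaults are calibrated once on the package's standard synthetic
#' benchmark (64 x 64 phantom, 9 x 9 LEDs, defocused pupil); none of
#' them follow from the physics, so all are explicit configuration.
#'
#' Two update rules are available for sample epochs.
#' `sample_update = "projection"` (default) applies per-LED relaxed
#' magnitude-replacement write-backs with the current pupil estimate:
#' this is gradient descent on the spectral loss in the pupil-window
#' metric with the natural unit step, and converges far faster than a
#' fixed-step gradient rule. `"gradient"` applies full-batch descent on
#' the Wirtinger gradients (useful for analysis; much slower).
#' Pupil epochs always use full-batch Wirtinger gradients of the
#' spectral loss with the chosen optimizer.
#'
#' @param epochs number of training epochs (each epoch processes all
#'   LEDs once); defaults to the length of `au_schedule`.
#' @param lr_sample sample step: relaxation factor in (0, 1] for
#'   `"projection"` (1 = full write-back), or the gradient-descent rate
#'   for `"gradient"`.
#' @param lr_pupil learning rate for the Zernike coefficients (and the
#'   CTF amplitude when it is learned) during pupil epochs.
#' @param optimizer `"adam"` (adaptive moments, default) or `"sgd"`
#'   (plain gradient descent) for the gradient-based updates. The pupil
#'   loss landscape is nearly flat early in training and sharply curved
#'   near convergence, so a fixed SGD step cannot serve both regimes;
#'   Adam's per-parameter scaling handles the transition.
#' @param sample_update `"projection"` or `"gradient"` (see Details).
#' @param delta Wirtinger step inside the WFM correction.
#' @param au_schedule alternation pattern from [iwf_au_schedule()], a
#'   character vector of `"sample"` / `"pupil"` recycled over epochs.
#' @param zernike_n_max maximum Zernike radial order of the pupil phase.
#' @param learn_ctf_amplitude also update the CTF amplitude during pupil
#'   epochs (projected non-negative after each step). Off by default:
#'   with a learnable amplitude the pupil-deconvolution write-back can
#'   amplify noise where the amplitude drifts small, and the package's
#'   defocus scenarios are phase-only.
#' @param detach_target treat phi_h as a fixed per-LED target rather
#'   than differentiating end-to-end through the WFM/WFN chain (the two
#'   gradients coincide analytically; see the methods vignette).
#' @param upsample_method intensity upsampling method (used when the phi
#'   grid is larger than the detector grid).
#' @param normalize normalize measured intensities to unit mean before
#'   training (the object scale is recovered up to that factor).
#' @param seed integer seed for any stochastic choice (the default
#'   initialization is deterministic).
#' @return a list of class `iwf_config`.
#' @export
iwf_config <- function(epochs = NULL, lr_sample = 1, lr_pupil = 0.05,
                       optimizer = c("adam", "sgd"),
                       sample_update = c("projection", "gradient"),
                       delta = 1, au_schedule = iwf_au_schedule(),
                       zernike_n_max = 4L, learn_ctf_amplitude = FALSE,
                       detach_target = FALSE,
                       upsample_method = "fourier", normalize = TRUE,
                       seed = 1L) {
  optimizer <- match.arg(optimizer)
  sample_update <- match.arg(sample_update)
  if (is.null(epochs)) epochs <- length(au_schedule)
  stopifnot(epochs >= 1L, lr_sample >= 0, lr_pupil >= 0, delta >= 0,
            all(au_schedule %in% c("sample", "pupil")))
  structure(list(epochs = as.integer(epochs), lr_sample = lr_sample,
                 lr_pupil = lr_pupil, optimizer = optimizer,
                 sample_update = sample_update,
                 delta = delta, au_schedule = au_schedule,
                 zernike_n_max = as.integer(zernike_n_max),
                 learn_ctf_amplitude = isTRUE(learn_ctf_amplitude),
                 detach_target = isTRUE(detach_target),
                 upsample_method = upsample_method,
                 normalize = isTRUE(normalize), seed = as.integer(seed)),
            class = "iwf_config")
}

#' Train the Wirtinger-Flow aberration-correcting reconstruction
#'
#' Gradient-descent training of the sample (real/imaginary maps) and the
#' pupil (CTF amplitude + Zernike phase coefficients) against the
#' spectral self-consistency loss, with the alternating-update schedule:
#' sample epochs touch only the sample block, pupil epochs only the
#' pupil block. Initialization is the Fourier-upsampled square root of
#' the most axial LED image for the sample and the ideal binary CTF with
#' zero Zernike coefficients for the pupil, unless `init` is supplied.
#'
#' @param stack an `fpm_stack`.
#' @param system an [fpm_system]; defaults to the stack's.
#' @param init an [iwf_params] to start from, or `NULL` for the default
#'   initialization.
#' @param config an [iwf_config()].
#' @return a list of class `fpm_iwf`: `object` (space-domain
#'   [complex_field]), recovered `pupil` ([build_pupil] object),
#'   `loss_trace` (numeric, loss before each epoch's update), `params`
#'   (final [iwf_params]), `config`, and `intensity_scale` (the mean
#'   intensity divided out when `normalize = TRUE`).
#' @export
train_inn_iwf <- function(stack, system = stack$system, init = NULL,
                          config = iwf_config()) {
  n_led <- dim(stack$images)[3]
  m <- system$lores_shape
  scale <- if (config$normalize) mean(stack$images) else 1
  if (scale <= 0) scale <- 1
  y <- lapply(seq_len(n_led), function(i) stack$images[, , i] / scale)
  sqrt_y <- lapply(y, sqrt)
  windows <- lapply(seq_len(n_led), function(i) {
    q <- quantize_shift(stack$wavevectors[i, ], system$dk)
    window_ranges(system$hires_shape, m, q$offset)
  })
  basis <- zernike_basis(system, zernike_terms(config$zernike_n_max))
  if (is.null(init)) {
    ctr <- which.min(rowSums(stack$wavevectors^2))
    big <- matrix(0 + 0i, system$hires_shape[1], system$hires_shape[2])
    w0 <- window_ranges(system$hires_shape, m)
    big[w0$rows, w0$cols] <- fft2c(sqrt_y[[ctr]])
    o0 <- ifft2c(big)
    init <- iwf_params(Re(o0), Im(o0), make_ctf(system),
                       numeric(nrow(basis$terms)), basis,
                       delta = config$delta)
  } else {
    basis <- init$basis
  }
  o_r <- init$sample_real; o_i <- init$sample_imag
  camp <- init$ctf_amplitude; coeffs <- init$zernike_coeffs
  sched <- rep_len(config$au_schedule, config$epochs)
  loss_trace <- numeric(config$epochs)
  opt <- list(or = adam_state(), oi = adam_state(), z = adam_state(),
              c = adam_state())
  adam <- config$optimizer == "adam"
  projection <- config$sample_update == "projection"
  for (ep in seq_len(config$epochs)) {
    theta <- zernike_phase(basis, coeffs)
    sample_ep <- sched[ep] == "sample"
    g <- iwf_batch_grad(o_r, o_i, camp, theta, basis, config$delta,
                        windows, y, sqrt_y,
                        detach_target = config$detach_target,
                        want_grad = !(sample_ep && projection))
    if (!is.finite(g$loss))
      stop("IWF training diverged (non-finite loss) at epoch ", ep,
           call. = FALSE)
    loss_trace[ep] <- g$loss
    if (sample_ep) {
      if (projection) {
        S <- fft2c(o_r + 1i * o_i)
        P <- camp * exp(1i * theta)
        upd <- Mod(P) > 1e-3
        alpha <- config$lr_sample
        for (n in seq_along(windows)) {
          w <- windows[[n]]
          phi <- S[w$rows, w$cols, drop = FALSE] * P
          gn <- sqrt_y[[n]] * exp(1i * Arg(ifft2c(phi)))
          patch <- fft2c(gn)
          old <- S[w$rows, w$cols]
          old[upd] <- (1 - alpha) * old[upd] + alpha * patch[upd] / P[upd]
          S[w$rows, w$cols] <- old
        }
        o <- ifft2c(S)
        o_r <- Re(o); o_i <- Im(o)
      } else if (adam) {
        opt$or <- adam_step(opt$or, g$g_sample_real, config$lr_sample)
        opt$oi <- adam_step(opt$oi, g$g_sample_imag, config$lr_sample)
        o_r <- o_r - opt$or$step
        o_i <- o_i - opt$oi$step
      } else {
        o_r <- o_r - config$lr_sample * g$g_sample_real
        o_i <- o_i - config$lr_sample * g$g_sample_imag
      }
    } else {
      if (adam) {
        opt$z <- adam_step(opt$z, g$g_zernike, config$lr_pupil)
        coeffs <- coeffs - opt$z$step
      } else {
        coeffs <- coeffs - config$lr_pupil * g$g_zernike
      }
      if (config$learn_ctf_amplitude) {
        if (adam) {
          opt$c <- adam_step(opt$c, g$g_ctf_amplitude, config$lr_pupil)
          camp <- camp - opt$c$step
        } else {
          camp <- camp - config$lr_pupil * g$g_ctf_amplitude
        }
        camp[camp < 0] <- 0
      }
    }
  }
  params <- iwf_params(o_r, o_i, camp, coeffs, basis,
                       delta = config$delta)
  pupil <- build_pupil(camp, basis, coeffs)
  obj <- complex_field((o_r + 1i * o_i) * sqrt(scale), "space",
                       system$pixel_size_obj)
  structure(list(object = obj, pupil = pupil, loss_trace = loss_trace,
                 params = params, config = config,
                 intensity_scale = scale, system = system),
            class = "fpm_iwf")
}
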