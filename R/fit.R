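#' Fit a high-resolution complex object to an FPM acquisition
#'
#' The central model-fitting front-end. Given a stack of low-resolution
#' intensity images, recovers the high-resolution complex object field
#' and — with the default `"iwf"` engine — the aberrated pupil function,
#' by gradient descent on the Wirtinger-Flow spectral self-consistency
#' loss with Zernike-parameterized pupil phase. The `"classic"` engine
#' runs the alternating-projection spectrum-stitching baseline with a
#' fixed, supplied pupil (no aberration correction).
#'
#' @param stack an `fpm_stack` from [simulate_dataset()] or
#'   [read_stack()].
#' @param method `"iwf"` (aberration-correcting) or `"classic"`.
#' @param system an [fpm_system]; defaults to the stack's.
#' @param config an [iwf_config()] (iwf engine).
#' @param pupil fixed pupil for the classic engine (default: ideal CTF).
#' @param n_iters sweeps for the classic engine.
#' @param ... further arguments passed to the engine.
#' @return an object of class `fpm_fit` with components `object` (the
#'   recovered space-domain [complex_field]), `pupil`, `method`,
#'   `trace`, `stack`, `system`, and the engine result in `engine`.
#'   Supports `print`, `summary`, `coef` (Zernike coefficients),
#'   `fitted` (per-LED model intensities), `residuals`, `predict`,
#'   `simulate`, and `plot`.
#' @examples
#' \donttest{
#' sys <- fpm_system(hires_shape = 32, upsampling = 2)
#' bench <- make_benchmark_case(z = 0, system = sys,
#'                              leds = led_array(c(3, 3)),
#'                              spec = phantom_spec(32))
#' fit <- fpm_fit(bench$stack, method = "classic", n_iters = 5)
#' fit
#' }
#' @export
fpm_fit <- function(stack, method = c("iwf", "classic"),
                    system = stack$system, config = iwf_config(),
                    pupil = NULL, n_iters = 50L, ...) {
  method <- match.arg(method)
  cl <- match.call()
  engine <- if (method == "iwf") {
    train_inn_iwf(stack, system, config = config, ...)
  } else {
    reconstruct_classic(stack, system, pupil = pupil,
                        n_iters = n_iters, ...)
  }
  trace <- if (method == "iwf") {
    data.frame(epoch = seq_along(engine$loss_trace),
               loss = engine$loss_trace)
  } else engine$trace
  structure(list(object = engine$object, pupil = engine$pupil,
                 method = method, trace = trace, engine = engine,
                 stack = stack, system = system, call = cl),
            class = "fpm_fit")
}

#' @export
print.fpm_fit <- function(x, ...) {
  d <- dim(x$object$values)
  cat(sprintf("FPM reconstruction (method: %s)\n", x$method))
  cat(sprintf("  object: %d x %d complex field from %d images\n",
              d[1], d[2], dim(x$stack$images)[3]))
  if (x$method == "iwf") {
    cat(sprintf("  final loss: %.4g after %d epochs\n",
                utils::tail(x$trace$loss, 1), nrow(x$trace)))
    cf <- coef(x)
    top <- order(abs(cf), decreasing = TRUE)[seq_len(min(3, length(cf)))]
    cat("  leading pupil terms (rad):",
        paste(sprintf("%s = %+.3f", names(cf)[top], cf[top]),
              collapse = ", "), "\n")
  } else {
    cat(sprintf("  %d sweeps, final intensity misfit %.4g\n",
                x$engine$iterations,
                utils::tail(x$trace$misfit, 1)))
  }
  invisible(x)
}

#' @export
summary.fpm_fit <- function(object, ...) {
  fit <- fitted(object)
  res <- object$stack$images - fit
  out <- list(method = object$method,
              n_images = dim(object$stack$images)[3],
              object_dim = dim(object$object$values),
              coef = coef(object),
              trace = object$trace,
              rmse_intensity = sqrt(mean(res^2)))
  class(out) <- "summary.fpm_fit"
  out
}

#' @export
print.summary.fpm_fit <- function(x, ...) {
  cat(sprintf("FPM fit summary (%s): %d images -> %d x %d object\n",
              x$method, x$n_images, x$object_dim[1], x$object_dim[2]))
  cat(sprintf("  intensity RMSE (refit): %.4g\n", x$rmse_intensity))
  if (length(x$coef)) {
    cat("  pupil Zernike coefficients (rad):\n")
    print(round(x$coef, 4))
  }
  invisible(x)
}

#' @export
coef.fpm_fit <- function(object, ...) {
  p <- object$pupil
  cf <- p$zernike_coeffs
  names(cf) <- sprintf("Z(%d,%+d)", p$basis$terms$n, p$basis$terms$m)
  cf
}

#' @export
fitted.fpm_fit <- function(object, ...) {
  sc <- if (object$method == "iwf") object$engine$intensity_scale else 1
  S <- fft2c(object$object$values / sqrt(sc))
  n <- nrow(object$stack$wavevectors)
  m <- object$system$lores_shape
  out <- array(0, c(m[1], m[2], n))
  for (i in seq_len(n))
    out[, , i] <- forward_image(S, object$pupil,
                                object$stack$wavevectors[i, ],
                                object$system) * sc
  out
}

#' @export
residuals.fpm_fit <- function(object, ...) {
  object$stack$images - fitted(object)
}

#' Predict low-resolution intensities for new illumination angles
#'
#' @param object an `fpm_fit`.
#' @param newdata an [led_array], or a numeric n x 2 matrix of wave
#'   vectors (cycles/um); default: the fitted stack's wave vectors.
#' @param ... unused.
#' @return array of predicted intensity images.
#' @export
predict.fpm_fit <- function(object, newdata = NULL, ...) {
  wv <- if (is.null(newdata)) {
    object$stack$wavevectors
  } else if (inherits(newdata, "led_array")) {
    newdata$wavevectors
  } else as.matrix(newdata)
  sc <- if (object$method == "iwf") object$engine$intensity_scale else 1
  S <- fft2c(object$object$values / sqrt(sc))
  m <- object$system$lores_shape
  out <- array(0, c(m[1], m[2], nrow(wv)))
  for (i in seq_len(nrow(wv)))
    out[, , i] <- forward_image(S, object$pupil, wv[i, ],
                                object$system) * sc
  out
}

#' Simulate new acquisition stacks from a fitted model
#'
#' @param object an `fpm_fit`.
#' @param nsim number of stacks.
#' @param seed RNG seed (used when noise is requested).
#' @param noise a [noise_spec()] or `NULL`.
#' @param ... unused.
#' @return a list of `fpm_stack` objects.
#' @export
simulate.fpm_fit <- function(object, nsim = 1, seed = NULL,
                             noise = NULL, ...) {
  leds <- object$stack$leds
  lapply(seq_len(nsim), function(i)
    simulate_dataset(object$object, object$pupil, leds, object$system,
                     noise = noise,
                     seed = if (is.null(seed)) NULL else seed + i - 1L))
}

#' Plot an FPM reconstruction
#'
#' Panels: recovered amplitude, recovered phase, recovered pupil phase,
#' and the optimization trace.
#'
#' @param x an `fpm_fit`.
#' @param ... passed to [graphics::image()].
#' @export
plot.fpm_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(2.5, 2.5, 2, 1))
  on.exit(graphics::par(op))
  gray <- grDevices::gray.colors(256, 0, 1)
  img <- function(z, main) graphics::image(
    t(z[rev(seq_len(nrow(z))), ]), col = gray, axes = FALSE,
    main = main, useRaster = TRUE, ...)
  img(Mod(x$object$values), "amplitude")
  img(Arg(x$object$values), "phase")
  img(x$pupil$phase, "pupil phase (rad)")
  yl <- if (x$method == "iwf") "loss" else "misfit"
  yv <- if (x$method == "iwf") x$trace$loss else x$trace$misfit
  graphics::plot(seq_along(yv), yv, type = "l", log = "y",
                 xlab = "epoch", ylab = yl, main = "trace")
  invisible(x)
}
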