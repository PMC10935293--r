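# Image-quality metrics: PSNR from MSE on unit-range images, and SSIM
# from luminance / contrast / structure statistics, either globally
# (one statistic from whole-image moments) or averaged over sliding
# windows.

#' Peak signal-to-noise ratio
#'
#' PSNR = -10 log10(mean((I1 - I2)^2)) for images on the [0, 1] scale
#' (no separate peak term: peak = 1). Identical images give `Inf`.
#'
#' @param reference,test numeric matrices of the same shape, scaled to
#'   [0, 1].
#' @param rescale_warn warn when inputs stray outside [0, 1].
#' @return PSNR in dB (`Inf` when the images are identical).
#' @examples
#' psnr(matrix(0.5, 4, 4), matrix(0.6, 4, 4))  # mse 0.01 -> 20 dB
#' @export
psnr <- function(reference, test, rescale_warn = TRUE) {
  if (!all(dim(reference) == dim(test)))
    stop("images must share a shape", call. = FALSE)
  if (rescale_warn &&
      (min(reference, test) < -1e-9 || max(reference, test) > 1 + 1e-9))
    warning("psnr assumes images scaled to [0, 1]; values fall outside")
  mse <- mean((reference - test)^2)
  if (mse == 0) Inf else -10 * log10(mse)
}

# SSIM statistic from precomputed moments.
#' @keywords internal
ssim_stat <- function(mu1, mu2, v1, v2, cov12, c1, c2) {
  ((2 * mu1 * mu2 + c1) * (2 * cov12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
}

#' Structural similarity index
#'
#' Global mode computes the SSIM statistic
#' (2 mu1 mu2 + C1)(2 sigma12 + C2) /
#' ((mu1^2 + mu2^2 + C1)(sigma1^2 + sigma2^2 + C2))
#' from whole-image means, variances and covariance; windowed mode
#' averages the same statistic over all fully-interior sliding windows
#' (default 7 x 7, uniform weights). The stabilizing constants default
#' to C1 = (0.01 L)^2, C2 = (0.03 L)^2 with dynamic range L = 1; setting
#' them equal is supported via the arguments. The result lies in
#' [-1, 1]; anti-correlated fluctuations give negative values.
#'
#' @param reference,test numeric matrices of the same shape.
#' @param c1,c2 positive stabilizing constants.
#' @param mode `"global"` or `"windowed"`.
#' @param window odd window side for windowed mode.
#' @return SSIM value.
#' @export
ssim <- function(reference, test, c1 = 1e-4, c2 = 9e-4,
                 mode = c("global", "windowed"), window = 7L) {
  mode <- match.arg(mode)
  if (!all(dim(reference) == dim(test)))
    stop("images must share a shape", call. = FALSE)
  stopifnot(c1 > 0, c2 > 0)
  if (mode == "global") {
    n <- length(reference)
    mu1 <- mean(reference); mu2 <- mean(test)
    v1 <- sum((reference - mu1)^2) / (n - 1)
    v2 <- sum((test - mu2)^2) / (n - 1)
    cov12 <- sum((reference - mu1) * (test - mu2)) / (n - 1)
    return(ssim_stat(mu1, mu2, v1, v2, cov12, c1, c2))
  }
  w <- as.integer(window)
  if (w > min(dim(reference)))
    stop("window larger than the image", call. = FALSE)
  # uniform-filter local moments via cumulative sums
  box <- function(x) {
    cs <- apply(apply(x, 2L, cumsum), 1L, cumsum)  # transposed cumsum
    cs <- t(cs)
    pad <- matrix(0, nrow(x) + 1L, ncol(x) + 1L)
    pad[-1L, -1L] <- cs
    nr <- nrow(x) - w + 1L; nc <- ncol(x) - w + 1L
    pad[(w + 1L):(nrow(x) + 1L), (w + 1L):(ncol(x) + 1L)] -
      pad[1L:nr, (w + 1L):(ncol(x) + 1L)] -
      pad[(w + 1L):(nrow(x) + 1L), 1L:nc] + pad[1L:nr, 1L:nc]
  }
  np <- w * w
  s1 <- box(reference); s2 <- box(test)
  s11 <- box(reference^2); s22 <- box(test^2)
  s12 <- box(reference * test)
  mu1 <- s1 / np; mu2 <- s2 / np
  v1 <- (s11 - np * mu1^2) / (np - 1)
  v2 <- (s22 - np * mu2^2) / (np - 1)
  cov12 <- (s12 - np * mu1 * mu2) / (np - 1)
  mean(ssim_stat(mu1, mu2, v1, v2, cov12, c1, c2))
}

#' Normalize an image to [0, 1]
#'
#' Affine rescaling used before amplitude comparisons; a constant image
#' maps to all zeros.
#'
#' @param x numeric matrix.
#' @return matrix with values in [0, 1].
#' @export
normalize01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Amplitude and phase quality report for a reconstruction
#'
#' Compares a reconstructed complex field against the ground truth:
#' amplitudes are each normalized to [0, 1] before PSNR/SSIM (the global
#' intensity scale is not identifiable from intensity-only data), and
#' the phase is affinely aligned to the reference range first (a global
#' phase offset is likewise unidentifiable).
#'
#' @param truth,estimate space-domain [complex_field]s (or complex
#'   matrices) on the same grid.
#' @param ssim_mode `"windowed"` (default, table-style) or `"global"`.
#' @return a data frame row with `psnr_amp`, `ssim_amp`, `psnr_phase`,
#'   `ssim_phase`, `mse_amp`.
#' @export
evaluate_reconstruction <- function(truth, estimate,
                                    ssim_mode = "windowed") {
  tv <- field_values(truth); ev <- field_values(estimate)
  amp_t <- normalize01(Mod(tv)); amp_e <- normalize01(Mod(ev))
  ph_t <- Arg(tv); ph_e <- Arg(ev)
  # align estimate phase affinely onto the reference range
  ph_en <- normalize01(ph_e)
  rt <- range(ph_t)
  ph_ea <- ph_en * (rt[2] - rt[1]) + rt[1]
  pt01 <- normalize01(ph_t); pe01 <- normalize01(ph_ea)
  data.frame(
    psnr_amp = psnr(amp_t, amp_e),
    ssim_amp = ssim(amp_t, amp_e, mode = ssim_mode),
    psnr_phase = psnr(pt01, pe01),
    ssim_phase = ssim(pt01, pe01, mode = ssim_mode),
    mse_amp = mean((amp_t - amp_e)^2)
  )
}
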