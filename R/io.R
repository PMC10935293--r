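# Input/output: acquisition stacks as multi-page TIFF with a JSON
# geometry sidecar, reconstructions as float TIFF + CSV + JSON metadata,
# Zernike coefficient tables as CSV, and run configuration as YAML/JSON.

#' Write an acquisition stack to disk
#'
#' Images go to one multi-page 32-bit float TIFF (one page per LED, scan
#' order); the geometry, wave vectors, noise settings and seed go to a
#' JSON sidecar next to it. Frequency-domain arrays use the centered
#' layout with pixel (1,1) top-left; the sidecar records this.
#'
#' @param stack an `fpm_stack`.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  n <- dim(stack$images)[3]
  # TIFF pages hold values in [0, 1] at 32-bit resolution; the physical
  # intensity scale is recorded in the sidecar
  vmax <- max(stack$images, 1e-300)
  pages <- lapply(seq_len(n), function(i) stack$images[, , i] / vmax)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sys <- stack$system
  meta <- list(
    format = "fpmflow-stack-v1",
    layout = "centered frequency grids; pixel (1,1) is top-left",
    n_images = n,
    intensity_max = vmax,
    wavevectors = unname(apply(stack$wavevectors, 1L, as.numeric,
                               simplify = FALSE)),
    system = list(wavelength = sys$wavelength, na = sys$na,
                  pixel_size_obj = sys$pixel_size_obj,
                  hires_shape = sys$hires_shape,
                  upsampling = sys$upsampling),
    leds = if (!is.null(stack$leds)) list(
      grid_shape = stack$leds$grid_shape, pitch = stack$leds$pitch,
      height = stack$leds$height,
      center_offset = stack$leds$center_offset) else NULL,
    noise = stack$noise, seed = stack$seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an acquisition stack
#'
#' Accepts the multi-page TIFF + JSON sidecar written by
#' [write_stack()], or a directory of numbered single-image TIFF/PNG
#' files with a `manifest.json` of the same schema. Integer images are
#' rescaled to [0, 1] by their type maximum (the `tiff` package already
#' applies this convention).
#'
#' @param path TIFF file or directory.
#' @return an `fpm_stack`.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    manifest <- file.path(path, "manifest.json")
    if (!file.exists(manifest))
      stop("stack directory has no manifest.json", call. = FALSE)
    meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             full.names = TRUE, ignore.case = TRUE))
    pages <- lapply(files, read_image_any)
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("missing sidecar JSON for stack: ", sidecar, call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
  }
  wv <- meta$wavevectors
  if (is.list(wv)) wv <- do.call(rbind, wv)
  wv <- matrix(as.numeric(wv), ncol = 2)
  colnames(wv) <- c("kx", "ky")
  if (length(pages) != nrow(wv))
    stop("manifest lists ", nrow(wv), " wave vectors but ",
         length(pages), " images were found", call. = FALSE)
  sysm <- meta$system
  system <- fpm_system(sysm$wavelength, sysm$na, sysm$pixel_size_obj,
                       as.integer(sysm$hires_shape),
                       as.integer(sysm$upsampling))
  m <- dim(pages[[1]])
  vmax <- if (!is.null(meta$intensity_max)) meta$intensity_max else 1
  imgs <- array(0, c(m[1], m[2], length(pages)))
  for (i in seq_along(pages)) imgs[, , i] <- pages[[i]] * vmax
  structure(list(images = imgs, wavevectors = wv,
                 residuals = NULL, system = system, leds = NULL,
                 noise = meta$noise, seed = meta$seed),
            class = "fpm_stack")
}

#' @keywords internal
read_image_any <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(f)
  else if (ext == "png" && requireNamespace("png", quietly = TRUE))
    png::readPNG(f)
  else stop("unsupported image file: ", f, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a reconstruction to a directory
#'
#' Emits `amplitude.tiff` and `phase.tiff` (32-bit float; phase in
#' radians within (-pi, pi]), `pupil_amplitude.tiff`, the Zernike
#' coefficient table `zernike.csv`, the optimization `trace.csv`, and a
#' `run.json` with enough metadata to re-run the fit.
#'
#' @param fit an `fpm_fit` (or a list with `object` and `pupil`).
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_reconstruction <- function(fit, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ov <- field_values(fit$object)
  wtif <- function(x, f) tiff::writeTIFF(x, file.path(outdir, f),
                                         bits.per.sample = 32L)
  # amplitudes scaled into [0, 1] (scale in run.json); phase mapped from
  # (-pi, pi] onto [0, 1)
  amp_max <- max(Mod(ov), 1e-300)
  pup_max <- max(fit$pupil$amplitude, 1e-300)
  wtif(Mod(ov) / amp_max, "amplitude.tiff")
  wtif((Arg(ov) + pi) / (2 * pi), "phase.tiff")
  wtif(fit$pupil$amplitude / pup_max, "pupil_amplitude.tiff")
  write_zernike_csv(fit$pupil$basis$terms, fit$pupil$zernike_coeffs,
                    file.path(outdir, "zernike.csv"))
  if (!is.null(fit$trace))
    utils::write.csv(fit$trace, file.path(outdir, "trace.csv"),
                     row.names = FALSE)
  sys <- fit$system
  meta <- list(package = "fpmflow",
               version = as.character(utils::packageVersion("fpmflow")),
               method = fit$method,
               system = list(wavelength = sys$wavelength, na = sys$na,
                             pixel_size_obj = sys$pixel_size_obj,
                             hires_shape = sys$hires_shape,
                             upsampling = sys$upsampling),
               config = if (!is.null(fit$engine$config))
                 unclass(fit$engine$config) else NULL,
               amplitude_max = amp_max,
               pupil_amplitude_max = pup_max,
               phase_convention =
                 "stored as (phase + pi) / (2 pi); radians in (-pi, pi]")
  jsonlite::write_json(meta, file.path(outdir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' Read a reconstruction directory back as a complex field
#'
#' Inverts the scaling conventions of [write_reconstruction()].
#'
#' @param outdir directory written by [write_reconstruction()].
#' @return a space-domain [complex_field].
#' @export
read_reconstruction <- function(outdir) {
  meta <- jsonlite::read_json(file.path(outdir, "run.json"),
                              simplifyVector = TRUE)
  amp <- tiff::readTIFF(file.path(outdir, "amplitude.tiff")) *
    meta$amplitude_max
  ph <- tiff::readTIFF(file.path(outdir, "phase.tiff")) * 2 * pi - pi
  complex_field(amp * exp(1i * ph), "space")
}

#' Zernike coefficient tables as CSV
#'
#' Columns `j`, `n`, `m`, `coeff_rad`; [read_zernike_csv()] reproduces
#' the coefficient vector exactly.
#'
#' @param terms a term table from [zernike_terms()].
#' @param coeffs coefficient vector, radians.
#' @param path CSV path.
#' @return `path` invisibly / a list with `terms` and `coeffs`.
#' @export
write_zernike_csv <- function(terms, coeffs, path) {
  stopifnot(nrow(terms) == length(coeffs))
  # 17 significant digits make the decimal round-trip exact for doubles
  tab <- data.frame(j = terms$j, n = terms$n, m = terms$m,
                    coeff_rad = sprintf("%.17g", coeffs))
  utils::write.table(tab, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_zernike_csv
#' @export
read_zernike_csv <- function(path) {
  tab <- utils::read.csv(path)
  list(terms = tab[c("j", "n", "m")],
       coeffs = as.numeric(tab$coeff_rad))
}

#' Read a run configuration file
#'
#' YAML or JSON nested key-value document with sections among `system`,
#' `leds`, `phantom`, `training`, `metrics`, `paths`. Unknown top-level
#' sections are rejected.
#'
#' @param path config file (.yaml/.yml/.json).
#' @return named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be YAML or JSON: ", path, call. = FALSE)
  known <- c("system", "leds", "phantom", "training", "metrics", "paths",
             "seed", "defocus_um", "noise")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config sections: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}
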