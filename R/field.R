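#' Two-dimensional complex field
#'
#' A light container for a 2-D complex amplitude: either a space-domain
#' field (an object transmission function, a detected complex amplitude)
#' or a centered frequency-domain spectrum. The sampling pitch is carried
#' along so that transforms and pupil geometry stay consistent.
#'
#' @param values numeric or complex matrix.
#' @param domain `"space"` or `"frequency"`.
#' @param sampling pixel pitch: micrometres per pixel in the space domain,
#'   cycles per micrometre per pixel in the frequency domain.
#' @return an object of class `complex_field`.
#' @export
complex_field <- function(values, domain = c("space", "frequency"),
                          sampling = NULL) {
  domain <- match.arg(domain)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  structure(list(values = values + 0i, domain = domain, sampling = sampling),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<complex_field> %d x %d, %s domain", d[1], d[2], x$domain))
  if (!is.null(x$sampling)) {
    unit <- if (x$domain == "space") "um/px" else "cyc/um/px"
    cat(sprintf(", sampling %.4g %s", x$sampling, unit))
  }
  cat(sprintf("\n  |.| in [%.3g, %.3g]\n",
              min(Mod(x$values)), max(Mod(x$values))))
  invisible(x)
}

#' @export
Re.complex_field <- function(z) Re(z$values)

#' @export
Im.complex_field <- function(z) Im(z$values)

#' @export
Mod.complex_field <- function(z) Mod(z$values)

#' @export
Arg.complex_field <- function(z) Arg(z$values)

#' @export
dim.complex_field <- function(x) dim(x$values)

# Transform between domains, preserving the sampling relation
# dk = 1 / (n * dx).
#' @rdname complex_field
#' @param field a `complex_field`.
#' @export
to_frequency <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  if (field$domain == "frequency") return(field)
  n <- nrow(field$values)
  dk <- if (is.null(field$sampling)) NULL else 1 / (n * field$sampling)
  complex_field(fft2c(field$values), "frequency", dk)
}

#' @rdname complex_field
#' @export
to_space <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  if (field$domain == "space") return(field)
  n <- nrow(field$values)
  dx <- if (is.null(field$sampling)) NULL else 1 / (n * field$sampling)
  complex_field(ifft2c(field$values), "space", dx)
}

#' @keywords internal
field_values <- function(x) {
  if (inherits(x, "complex_field")) x$values else x
}
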