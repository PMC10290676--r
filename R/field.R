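#' Complex wavefront on a physical grid
#'
#' A `complex_field` is a sampled 2-D complex amplitude (dimensionless
#' transmission units) together with the physical sampling metadata needed
#' for free-space propagation: the pixel pitch and the illumination
#' wavelength, both in metres.
#'
#' @param values Complex (or real, promoted to complex) matrix of samples.
#' @param pitch Pixel pitch in metres (> 0).
#' @param wavelength Illumination wavelength in metres (> 0).
#'
#' @return An object of class `complex_field`: a list with elements
#'   `values`, `pitch`, `wavelength`.
#' @examples
#' u <- complex_field(matrix(1 + 0i, 64, 64), pitch = 5.86e-6,
#'                    wavelength = 500e-9)
#' @export
complex_field <- function(values, pitch, wavelength) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.numeric(values)) storage.mode(values) <- "complex"
  if (!is.complex(values)) stop("`values` must be numeric or complex")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("field must be at least 2 x 2")
  if (anyNA(values) || any(!is.finite(Re(values)) | !is.finite(Im(values))))
    stop("field values must be finite")
  check_positive_scalar(pitch, "pitch")
  check_positive_scalar(wavelength, "wavelength")
  structure(list(values = values, pitch = pitch, wavelength = wavelength),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf(
    "<complex_field> %d x %d, pitch %.3g um, wavelength %.4g nm\n",
    nrow(x$values), ncol(x$values), x$pitch * 1e6, x$wavelength * 1e9))
  invisible(x)
}

#' @export
dim.complex_field <- function(x) dim(x$values)

#' Single in-line hologram measurement
#'
#' A `hologram` holds the nonnegative intensity image recorded by the
#' sensor plus the acquisition metadata: pixel pitch, wavelength and the
#' nominal object-to-sensor distance.
#'
#' @param intensity Nonnegative real matrix.
#' @param pitch Pixel pitch in metres.
#' @param wavelength Wavelength in metres.
#' @param z Object-to-sensor distance in metres (may be `NA` if unknown;
#'   reconstruction functions then require an explicit `z`).
#' @param bit_depth Optional integer bit depth of the originating file.
#'
#' @return An object of class `hologram`.
#' @examples
#' h <- hologram(matrix(1, 32, 32), pitch = 5.86e-6, wavelength = 500e-9,
#'               z = 0.06)
#' @export
hologram <- function(intensity, pitch, wavelength, z = NA_real_,
                     bit_depth = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity must be finite")
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  check_positive_scalar(pitch, "pitch")
  check_positive_scalar(wavelength, "wavelength")
  structure(list(intensity = intensity, pitch = pitch,
                 wavelength = wavelength, z = z, bit_depth = bit_depth),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf(
    "<hologram> %d x %d, pitch %.3g um, wavelength %.4g nm, z = %s\n",
    nrow(x$intensity), ncol(x$intensity), x$pitch * 1e6,
    x$wavelength * 1e9,
    if (is.na(x$z)) "unknown" else sprintf("%.4g cm", x$z * 100)))
  invisible(x)
}

#' @export
dim.hologram <- function(x) dim(x$intensity)

#' Amplitude and phase of a complex field
#'
#' @param field A [complex_field].
#' @return `field_amplitude()` returns `Mod(values)`; `field_phase()`
#'   returns `Arg(values)` wrapped to (-pi, pi].
#' @export
field_amplitude <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  Mod(field$values)
}

#' @rdname field_amplitude
#' @export
field_phase <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  Arg(field$values)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name))
  invisible(TRUE)
}

# wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
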