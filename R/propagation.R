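#' Spatial-frequency grid for a sampled field
#'
#' Frequency coordinates in cycles per metre, in standard (unshifted) DFT
#' ordering, for a grid of `shape` samples at pixel pitch `pitch`.  The
#' spacing is `1/(N * pitch)` per axis and the largest magnitude is the
#' Nyquist frequency `1/(2 * pitch)`.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param pitch Pixel pitch in metres.
#' @return List with matrices `fx` (varies along columns), `fy` (varies
#'   along rows) and `f2 = fx^2 + fy^2`.
#' @export
frequency_grid <- function(shape, pitch) {
  check_positive_scalar(pitch, "pitch")
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 2L))
  f1 <- function(n) {
    k <- 0:(n - 1L)
    ((k + n %/% 2L) %% n - n %/% 2L) / (n * pitch)
  }
  fy <- matrix(f1(shape[1L]), shape[1L], shape[2L])
  fx <- matrix(f1(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  list(fx = fx, fy = fy, f2 = fx^2 + fy^2)
}

#' Angular-spectrum transfer function
#'
#' The free-space transfer function
#' `H = exp(i 2 pi z sqrt(1/lambda^2 - fx^2 - fy^2))` on the propagating
#' band `fx^2 + fy^2 <= 1/lambda^2`, and exactly zero on the evanescent
#' remainder.  `|H| = 1` inside the band, so propagation is unitary for
#' band-limited fields.
#'
#' @param grid A frequency grid from [frequency_grid()].
#' @param z Propagation distance in metres (negative = back-propagation).
#' @param wavelength Wavelength in metres.
#' @return Complex matrix of the same shape as the grid.
#' @export
transfer_function <- function(grid, z, wavelength) {
  check_positive_scalar(wavelength, "wavelength")
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z))
  arg <- 1 / wavelength^2 - grid$f2
  H <- matrix(0 + 0i, nrow(arg), ncol(arg))
  inband <- arg >= 0
  H[inband] <- exp(2i * pi * z * sqrt(arg[inband]))
  H
}

#' Propagate a complex field through free space
#'
#' Band-limited angular-spectrum propagation
#' `P_z(u) = IFFT( FFT(u) * H(fx, fy, z) )` on the field's own grid.
#' Energy is conserved for fields with no evanescent spectral content and
#' `propagate(u, 0)` is the identity.  When part of the sampled frequency
#' grid lies beyond `1/wavelength` (possible when `wavelength > 2 * pitch`)
#' those components are zeroed and a warning is emitted once per call.
#'
#' @param field A [complex_field].
#' @param z Distance in metres (signed).
#' @return A [complex_field] on the same grid.
#' @examples
#' u <- complex_field(matrix(1 + 0i, 64, 64), 5.86e-6, 500e-9)
#' v <- propagate(u, 0.06)   # plane wave: only a global phase changes
#' @export
propagate <- function(field, z) {
  stopifnot(inherits(field, "complex_field"))
  grid <- frequency_grid(dim(field$values), field$pitch)
  if (max(grid$f2) > 1 / field$wavelength^2)
    warning("sampled frequencies extend into the evanescent region; ",
            "those components are zeroed", call. = FALSE)
  H <- transfer_function(grid, z, field$wavelength)
  out <- stats::fft(stats::fft(field$values) * H, inverse = TRUE) /
    length(field$values)
  complex_field(out, field$pitch, field$wavelength)
}

#' Pad an image with a constant, centred
#'
#' Centres the input in a `target_shape` canvas filled with `fill`; for odd
#' size differences the extra row/column goes to the bottom/right.  The
#' placement is recorded in attributes `pad_offset` (top-left index of the
#' original content, 1-based) and `pad_original` (original shape) so that
#' [unpad()] is the exact inverse.
#'
#' @param x Real or complex matrix.
#' @param target_shape `c(rows, cols)`, each >= the input's.
#' @param fill Scalar fill value.
#' @return Padded matrix with attributes `pad_offset`, `pad_original`.
#' @export
pad_constant <- function(x, target_shape, fill = 0) {
  stopifnot(is.matrix(x))
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 2L)
  if (any(target_shape < dim(x)))
    stop("`target_shape` must be at least the input shape on both axes")
  off <- (target_shape - dim(x)) %/% 2L
  fill <- as.vector(fill)[1L]
  if (is.complex(x) || is.complex(fill)) {
    fill <- as.complex(fill)
  } else if (is.integer(x) && fill == round(fill)) {
    fill <- as.integer(fill)        # keep integer inputs exactly integer
  } else {
    fill <- as.double(fill)
  }
  out <- matrix(fill, target_shape[1L], target_shape[2L])
  out[off[1L] + seq_len(nrow(x)), off[2L] + seq_len(ncol(x))] <- x
  attr(out, "pad_offset") <- off + 1L
  attr(out, "pad_original") <- dim(x)
  out
}

#' @rdname pad_constant
#' @param shape,offset Shape and top-left offset of the region to extract;
#'   default to the attributes recorded by [pad_constant()].
#' @export
unpad <- function(x, shape = attr(x, "pad_original"),
                  offset = attr(x, "pad_offset")) {
  stopifnot(is.matrix(x), !is.null(shape), !is.null(offset))
  x[offset[1L] + seq_len(shape[1L]) - 1L,
    offset[2L] + seq_len(shape[2L]) - 1L, drop = FALSE]
}

#' Tamura coefficient of an intensity image
#'
#' `TC = sqrt(sd(I) / mean(I))` with the population standard deviation.
#' TC is invariant under multiplication of the image by a positive scalar
#' and is used as a sharpness criterion for numerical autofocus.
#'
#' @param intensity Nonnegative real matrix with positive mean.
#' @return Scalar Tamura coefficient.
#' @export
tamura_coefficient <- function(intensity) {
  stopifnot(is.numeric(intensity))
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  m <- mean(intensity)
  if (m <= 0) stop("degenerate input: image mean must be positive")
  s <- sqrt(mean((intensity - m)^2))
  sqrt(s / m)
}

#' Tamura-coefficient autofocus
#'
#' Back-propagates the hologram's amplitude (square root of the recorded
#' intensity) to each candidate distance and evaluates the Tamura
#' coefficient of the reconstructed amplitude.  The focus is the extremum
#' of the TC-versus-z curve; because the polarity of that extremum depends
#' on the object type (amplitude objects and phase objects differ), it can
#' be selected explicitly or detected as the global extremum farthest from
#' the median TC (`"auto"`, the default).
#'
#' @param holo A [hologram].
#' @param z_min,z_max Scan range in metres (`z_min < z_max`).
#' @param step Scan step in metres (> 0).
#' @param polarity `"auto"`, `"min"` or `"max"`.
#' @param refine_step Optional finer step; when given, a second scan with
#'   this step is run over one coarse step either side of the coarse
#'   optimum.
#' @return List with `z` (best distance), `z_coarse`, and `curve`, a
#'   data.frame of the coarse scan (`z`, `tc`).
#' @export
autofocus <- function(holo, z_min, z_max, step,
                      polarity = c("auto", "min", "max"),
                      refine_step = NULL) {
  stopifnot(inherits(holo, "hologram"))
  polarity <- match.arg(polarity)
  if (!(is.finite(z_min) && is.finite(z_max) && z_min < z_max))
    stop("need z_min < z_max")
  check_positive_scalar(step, "step")
  zs <- seq(z_min, z_max, by = step)
  tc <- tc_scan(holo, zs)
  best <- pick_extremum(tc, polarity)
  z_coarse <- zs[best]
  z_best <- z_coarse
  if (!is.null(refine_step)) {
    check_positive_scalar(refine_step, "refine_step")
    zf <- seq(max(z_min, z_coarse - step), min(z_max, z_coarse + step),
              by = refine_step)
    tcf <- tc_scan(holo, zf)
    z_best <- zf[pick_extremum(tcf, polarity)]
  }
  list(z = z_best, z_coarse = z_coarse,
       curve = data.frame(z = zs, tc = tc))
}

tc_scan <- function(holo, zs) {
  grid <- frequency_grid(dim(holo$intensity), holo$pitch)
  U <- stats::fft(sqrt(holo$intensity) + 0i)
  n <- length(U)
  vapply(zs, function(z) {
    H <- transfer_function(grid, -z, holo$wavelength)
    amp <- Mod(stats::fft(U * H, inverse = TRUE) / n)
    tamura_coefficient(amp)
  }, numeric(1L))
}

pick_extremum <- function(tc, polarity) {
  switch(polarity,
         min = which.min(tc),
         max = which.max(tc),
         auto = which.max(abs(tc - stats::median(tc))))
}
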