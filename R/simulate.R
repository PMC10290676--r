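#' Synthetic complex transmission objects
#'
#' Builds a complex object `u = A * exp(i * phi)` from rasterized
#' amplitude and phase patterns, returning the field together with the
#' ground-truth images and the object footprint used by mask-fidelity
#' metrics.
#'
#' Patterns: `"letters"` (block capitals from a built-in 5x7 font),
#' `"bars"` (three-bar resolution groups at several scales), `"blobs"`
#' (smoothed random ellipse unions with interior gradients, a stand-in
#' for cell-like specimens), `"disk"` (a single centred disk), `"none"`.
#' With `boundary = "flat"` the patterns sit on a uniform background
#' (amplitude `amp_range[2]`, phase `phase_range[1]`), so the object has
#' a well-defined support inside the frame.  With `boundary = "random"`
#' the scene fills the whole frame: the amplitude is a smooth random
#' texture spanning `amp_range` and the phase carries the sharp-edged
#' phase pattern — no clean support region exists, the regime where fixed
#' apertures are known to fail.
#'
#' @param shape Grid shape `c(rows, cols)`.
#' @param pitch,wavelength Physical metadata in metres.
#' @param amp_pattern,phase_pattern Pattern names (see above).
#' @param amp_text,phase_text Strings for `"letters"` patterns.
#' @param amp_range Amplitude range `c(min, max)` within `[0, 1]`;
#'   pattern pixels take `min` (absorbing), background `max`.
#' @param phase_range Phase range in radians; pattern pixels take `max`,
#'   background `min`.
#' @param boundary `"flat"` or `"random"`.
#' @param disk_radius Radius in pixels for `"disk"` patterns.
#' @param seed Seed for the random textures.
#' @return List of class `holo_scene`: `field` ([complex_field]),
#'   `amplitude`, `phase` (ground-truth matrices), `footprint` (logical),
#'   plus the generating parameters.
#' @examples
#' sc <- make_object(shape = c(128, 128), pitch = 5.86e-6,
#'                   wavelength = 500e-9)
#' @export
make_object <- function(shape = c(500L, 500L), pitch = 5.86e-6,
                        wavelength = 500e-9,
                        amp_pattern = c("letters", "bars", "blobs",
                                        "disk", "none"),
                        phase_pattern = c("letters", "bars", "blobs",
                                          "disk", "none"),
                        amp_text = "HOLO", phase_text = "CELL",
                        amp_range = c(0.4, 1), phase_range = c(0, 1),
                        boundary = c("flat", "random"),
                        disk_radius = NULL, seed = 1L) {
  amp_pattern <- match.arg(amp_pattern)
  phase_pattern <- match.arg(phase_pattern)
  boundary <- match.arg(boundary)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 16L),
            length(amp_range) == 2L, length(phase_range) == 2L,
            amp_range[1L] <= amp_range[2L],
            phase_range[1L] <= phase_range[2L],
            amp_range[1L] >= 0, amp_range[2L] <= 1)
  set.seed(as.integer(seed))
  if (is.null(disk_radius)) disk_radius <- round(min(shape) / 8)

  rast <- function(pattern, text, region = 1L) {
    switch(pattern,
           none = matrix(FALSE, shape[1L], shape[2L]),
           letters = raster_letters(shape, text, region),
           bars = raster_bars(shape, region),
           blobs = raster_blobs(shape),
           disk = support_mask(shape, "circle",
                               center = round(shape / 2),
                               radius = disk_radius))
  }
  amp_px <- rast(amp_pattern, amp_text, region = 1L)
  ph_px <- rast(phase_pattern, phase_text, region = 2L)

  if (boundary == "flat") {
    amplitude <- matrix(amp_range[2L], shape[1L], shape[2L])
    amplitude[amp_px] <- amp_range[1L]
    phase <- matrix(phase_range[1L], shape[1L], shape[2L])
    phase[ph_px] <- phase_range[2L]
    footprint <- amp_px | ph_px
  } else {
    # "random" boundary: the scene fills the whole frame - a smooth
    # random amplitude texture spanning amp_range with a sharp-edged
    # phase pattern on top, so no clean support region exists
    tex <- smooth_noise(shape, scale = min(shape) / 12)
    tex <- (tex - min(tex)) / (max(tex) - min(tex))
    amplitude <- matrix(amp_range[1L], shape[1L], shape[2L]) +
      tex * diff(amp_range)
    ph_px <- rast(phase_pattern, phase_text, region = 1L)
    phase <- matrix(phase_range[1L], shape[1L], shape[2L])
    phase[ph_px] <- phase_range[2L]
    footprint <- matrix(TRUE, shape[1L], shape[2L])
  }
  values <- matrix(complex(modulus = as.vector(amplitude),
                           argument = as.vector(phase),
                           length.out = length(amplitude)),
                   shape[1L], shape[2L])
  structure(list(field = complex_field(values, pitch, wavelength),
                 amplitude = amplitude, phase = phase,
                 footprint = footprint,
                 amp_footprint = if (boundary == "flat") amp_px
                                 else footprint,
                 phase_footprint = ph_px,
                 pitch = pitch, wavelength = wavelength,
                 boundary = boundary, seed = seed),
            class = "holo_scene")
}

#' Standard simulation scene
#'
#' The reference simulation conditions used throughout the package's
#' validation: wavelength 500 nm, pixel pitch 5.86 um, a 500 x 500
#' hologram padded to 1000 x 1000 for reconstruction, recording distance
#' z = 6 cm, and a 0.5 mm plane interval for the multi-distance
#' baseline.
#'
#' @param object `"flat"` or `"random"` boundary style.
#' @param shape,pad_shape Hologram and working-grid shapes.
#' @param pitch,wavelength,z Physical parameters in metres.
#' @param mpr_interval Distance interval between MPR planes in metres.
#' @param seed Seed passed to [make_object()].
#' @param ... Further arguments to [make_object()].
#' @return A `holo_scene` with extra elements `z`, `pad_shape`,
#'   `mpr_z` (the three MPR plane distances).
#' @export
sim_scene <- function(object = c("flat", "random"),
                      shape = c(500L, 500L), pad_shape = c(1000L, 1000L),
                      pitch = 5.86e-6, wavelength = 500e-9, z = 0.06,
                      mpr_interval = 5e-4, seed = 1L, ...) {
  object <- match.arg(object)
  extra <- list(...)
  if (object == "random" && is.null(extra$phase_pattern))
    extra$phase_pattern <- "bars"   # the sharp-edged phase image
  sc <- do.call(make_object,
                c(list(shape = shape, pitch = pitch,
                       wavelength = wavelength, boundary = object,
                       seed = seed), extra))
  sc$z <- z
  sc$pad_shape <- as.integer(pad_shape)
  sc$mpr_z <- z + (0:2) * mpr_interval
  sc
}

#' Forward hologram formation
#'
#' Propagates the object transmission to the sensor plane with the
#' angular-spectrum method and records the intensity
#' `I = |P_z(u)|^2`.
#'
#' @param obj A [complex_field] (or a `holo_scene`, whose field is used).
#' @param z Recording distance in metres (> 0).
#' @return A [hologram] carrying the propagation metadata.
#' @export
forward_hologram <- function(obj, z) {
  if (inherits(obj, "holo_scene")) obj <- obj$field
  stopifnot(inherits(obj, "complex_field"))
  if (!is.numeric(z) || z <= 0) stop("`z` must be positive")
  us <- propagate(obj, z)
  hologram(Mod(us$values)^2, obj$pitch, obj$wavelength, z = z)
}

#' Additive white Gaussian noise at a stated SNR
#'
#' Adds zero-mean white Gaussian noise with variance
#' `mean(I^2) / 10^(snr_db / 10)` (signal power = mean squared clean
#' intensity) and clips the result at zero.
#'
#' @param holo A [hologram].
#' @param snr_db Signal-to-noise ratio in dB.
#' @param seed Seed (reproducible noise).
#' @return A noisy [hologram]; attributes `clipped_fraction` and
#'   `noise_sd` record the realized clipping fraction and the noise
#'   standard deviation.
#' @export
add_gaussian_noise <- function(holo, snr_db, seed = 1L) {
  stopifnot(inherits(holo, "hologram"), is.finite(snr_db))
  sd_n <- sqrt(mean(holo$intensity^2) / 10^(snr_db / 10))
  set.seed(as.integer(seed))
  noisy <- holo$intensity +
    matrix(stats::rnorm(length(holo$intensity), 0, sd_n),
           nrow(holo$intensity), ncol(holo$intensity))
  clipped <- mean(noisy < 0)
  noisy[noisy < 0] <- 0
  out <- hologram(noisy, holo$pitch, holo$wavelength, holo$z)
  attr(out, "clipped_fraction") <- clipped
  attr(out, "noise_sd") <- sd_n
  out
}

# --- pattern rasterizers -------------------------------------------------

smooth_noise <- function(shape, scale) {
  x <- matrix(stats::rnorm(prod(shape)), shape[1L], shape[2L])
  gaussian_smooth(x, sigma = scale / 3)
}

raster_blobs <- function(shape, n = 6L) {
  m <- matrix(0, shape[1L], shape[2L])
  rr <- row(m); cc <- col(m)
  for (i in seq_len(n)) {
    c0 <- stats::runif(2, 0.25, 0.75) * shape
    ax <- stats::runif(2, 0.03, 0.10) * min(shape)
    th <- stats::runif(1, 0, pi)
    dr <- rr - c0[1L]; dc <- cc - c0[2L]
    u <- cos(th) * dr + sin(th) * dc
    v <- -sin(th) * dr + cos(th) * dc
    m <- pmax(m, as.numeric((u / ax[1L])^2 + (v / ax[2L])^2 <= 1))
  }
  gaussian_smooth(m, 1) > 0.5
}

raster_bars <- function(shape, region = 1L) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  s <- min(shape)
  widths <- pmax(2L, round(s * c(0.030, 0.020, 0.012)))
  # region 1 = upper-left anchor, region 2 = lower-right anchor
  base <- if (region == 1L) round(shape * 0.22) else round(shape * 0.55)
  r0 <- base[1L]; c0 <- base[2L]
  for (w in widths) {
    for (b in 0:2) {                       # horizontal triplet
      rs <- r0 + b * 2L * w
      m[rs:(rs + w - 1L), c0:(c0 + 5L * w - 1L)] <- TRUE
    }
    cs <- c0 + 7L * w
    for (b in 0:2) {                       # vertical triplet
      csb <- cs + b * 2L * w
      m[r0:(r0 + 5L * w - 1L), csb:(csb + w - 1L)] <- TRUE
    }
    r0 <- r0 + 7L * w
  }
  m[seq_len(shape[1L]), seq_len(shape[2L])]
}

raster_letters <- function(shape, text, region = 1L) {
  glyphs <- letter_font()
  chars <- strsplit(toupper(text), "")[[1L]]
  chars <- chars[chars %in% names(glyphs)]
  if (length(chars) == 0L) stop("empty pattern: no renderable characters")
  # scale so the text spans ~55% of the width
  scale <- max(1L, floor(shape[2L] * 0.55 / (length(chars) * 6L)))
  gw <- 5L * scale; gh <- 7L * scale; gap <- scale
  total_w <- length(chars) * (gw + gap) - gap
  r0 <- if (region == 1L) round(shape[1L] * 0.30) - gh %/% 2L
        else round(shape[1L] * 0.68) - gh %/% 2L
  c0 <- (shape[2L] - total_w) %/% 2L
  m <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_along(chars)) {
    g <- glyphs[[chars[i]]]
    big <- g[rep(seq_len(7L), each = scale), rep(seq_len(5L), each = scale)]
    rs <- r0 + seq_len(gh); cs <- c0 + (i - 1L) * (gw + gap) + seq_len(gw)
    keep_r <- rs >= 1L & rs <= shape[1L]
    keep_c <- cs >= 1L & cs <= shape[2L]
    m[rs[keep_r], cs[keep_c]] <- m[rs[keep_r], cs[keep_c]] |
      big[keep_r, keep_c]
  }
  m
}

letter_font <- function() {
  g <- function(...) {
    rows <- c(...)
    matrix(as.logical(as.integer(strsplit(paste(rows, collapse = ""),
                                          "")[[1L]])), 7L, 5L, byrow = TRUE)
  }
  list(
    A = g("01110", "10001", "10001", "11111", "10001", "10001", "10001"),
    C = g("01110", "10001", "10000", "10000", "10000", "10001", "01110"),
    E = g("11111", "10000", "10000", "11110", "10000", "10000", "11111"),
    G = g("01110", "10001", "10000", "10111", "10001", "10001", "01110"),
    H = g("10001", "10001", "10001", "11111", "10001", "10001", "10001"),
    I = g("11111", "00100", "00100", "00100", "00100", "00100", "11111"),
    L = g("10000", "10000", "10000", "10000", "10000", "10000", "11111"),
    M = g("10001", "11011", "10101", "10101", "10001", "10001", "10001"),
    N = g("10001", "11001", "10101", "10011", "10001", "10001", "10001"),
    O = g("01110", "10001", "10001", "10001", "10001", "10001", "01110"),
    P = g("11110", "10001", "10001", "11110", "10000", "10000", "10000"),
    R = g("11110", "10001", "10001", "11110", "10100", "10010", "10001"),
    S = g("01111", "10000", "10000", "01110", "00001", "00001", "11110"),
    T = g("11111", "00100", "00100", "00100", "00100", "00100", "00100"),
    U = g("10001", "10001", "10001", "10001", "10001", "10001", "01110")
  )
}
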