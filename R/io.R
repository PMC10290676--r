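#' Read a hologram from a TIFF or PNG file
#'
#' Integer images are mapped to `[0, 1]` by dividing by the type maximum
#' (so the intensity scale is stable across frames of a multi-distance
#' stack); float TIFFs are taken as-is.  Multi-channel images are
#' rejected with a request to convert to grayscale.
#'
#' @param path Path to an 8/16-bit grayscale or float TIFF/PNG.
#' @param pitch,wavelength,z Acquisition metadata in metres (required;
#'   `z` may be `NA` if it is to be found by [autofocus()]).
#' @return A [hologram].
#' @export
read_hologram <- function(path, pitch, wavelength, z = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(pitch) || missing(wavelength))
    stop("metadata required: supply `pitch` and `wavelength` (metres)")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path, info = TRUE),
                png = png::readPNG(path),
                stop("unsupported format: ", ext,
                     " (use TIFF or PNG)"))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else stop("multi-channel image; convert to single-channel grayscale")
  }
  # readTIFF/readPNG already divide integer data by the type maximum;
  # float TIFFs come through unscaled.
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$intensity_scale)) img <- img * meta$intensity_scale
    if (is.na(z) && !is.null(meta$z_m)) z <- meta$z_m
  }
  hologram(img, pitch = pitch, wavelength = wavelength, z = z)
}

#' Write a complex field as amplitude + phase TIFFs with a sidecar
#'
#' Writes `<basename>_amplitude.tif` and `<basename>_phase.tif` as
#' 32-bit float TIFFs plus `<basename>_meta.yaml` recording the grid
#' metadata.  TIFF float samples are stored in `[0, 1]`, so the
#' amplitude is divided by `amp_scale = max(1, max(amplitude))` and the
#' phase (radians, wrapped to (-pi, pi]) is mapped to
#' `(phase + pi) / (2 pi)`; both mappings are recorded in the sidecar
#' and inverted by [read_field()].
#'
#' @param field A [complex_field].
#' @param basename Output path prefix.
#' @param extra Optional named list merged into the sidecar (e.g. the
#'   resolved run configuration).
#' @return Invisibly, the three paths written.
#' @export
write_field <- function(field, basename, extra = NULL) {
  stopifnot(inherits(field, "complex_field"))
  amp_path <- paste0(basename, "_amplitude.tif")
  ph_path <- paste0(basename, "_phase.tif")
  meta_path <- paste0(basename, "_meta.yaml")
  amp <- Mod(field$values)
  amp_scale <- max(1, max(amp))
  tiff::writeTIFF(amp / amp_scale, amp_path,
                  bits.per.sample = 32L, reduce = FALSE)
  ph01 <- (wrap_phase(Arg(field$values)) + pi) / (2 * pi)
  tiff::writeTIFF(ph01, ph_path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(list(rows = nrow(field$values), cols = ncol(field$values),
                 pitch_m = field$pitch, wavelength_m = field$wavelength,
                 amp_scale = amp_scale,
                 phase_encoding = "stored = (phase_rad + pi) / (2*pi)",
                 phase_units = "radians, wrapped to (-pi, pi]",
                 indexing = "row-major, origin top-left, 0-based in files"),
            extra)
  yaml::write_yaml(meta, meta_path)
  invisible(c(amplitude = amp_path, phase = ph_path, meta = meta_path))
}

#' Read back a field written by [write_field()]
#'
#' @param basename The prefix passed to [write_field()].
#' @return A [complex_field].
#' @export
read_field <- function(basename) {
  amp <- tiff::readTIFF(paste0(basename, "_amplitude.tif"))
  ph01 <- tiff::readTIFF(paste0(basename, "_phase.tif"))
  meta <- yaml::read_yaml(paste0(basename, "_meta.yaml"))
  amp <- amp * meta$amp_scale
  ph <- ph01 * 2 * pi - pi
  values <- matrix(complex(modulus = as.vector(amp),
                           argument = as.vector(ph),
                           length.out = length(amp)),
                   nrow(amp), ncol(amp))
  complex_field(values, meta$pitch_m, meta$wavelength_m)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write a hologram intensity image
#'
#' `"float"` writes 32-bit float samples; `"uint16"` quantizes to 16
#' bits.  TIFF samples live in `[0, 1]`, so intensities above 1 are
#' divided by `max(intensity)` and the divisor is stored in a
#' `<path>.yaml` sidecar, which [read_hologram()] applies on loading.
#'
#' @param holo A [hologram].
#' @param path Output TIFF path.
#' @param format `"float"` or `"uint16"`.
#' @export
write_hologram <- function(holo, path, format = c("float", "uint16")) {
  stopifnot(inherits(holo, "hologram"))
  format <- match.arg(format)
  mx <- max(holo$intensity)
  scale <- max(1, mx)
  tiff::writeTIFF(holo$intensity / scale, path,
                  bits.per.sample = if (format == "float") 32L else 16L,
                  reduce = FALSE)
  yaml::write_yaml(list(intensity_scale = scale, pitch_m = holo$pitch,
                        wavelength_m = holo$wavelength, z_m = holo$z),
                   paste0(path, ".yaml"))
  invisible(path)
}
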