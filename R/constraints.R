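#' Poisson-model minimum-error threshold
#'
#' Automatic, parameter-free binarization threshold: image values are
#' binned, the two classes induced by each candidate split are modelled as
#' Poisson populations with means fitted from the histogram, and the
#' candidate minimizing the total negative log-likelihood of the
#' classified histogram (minimum-error criterion) is returned.  The
#' log-factorial terms are class-independent and cancel across
#' candidates.
#'
#' @param x Nonnegative real matrix or vector with at least two distinct
#'   values.
#' @param bins Number of histogram bins used for non-integer data
#'   (integer-valued data keeps its native levels).
#' @return Scalar threshold on the scale of `x`; binarize as `x > thr`.
#' @examples
#' set.seed(1)
#' x <- c(rpois(1e4, 5), rpois(1e4, 50))
#' thr <- poisson_threshold(x)
#' @export
poisson_threshold <- function(x, bins = 256L) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("values must be nonnegative")
  rng <- range(x)
  if (rng[1L] == rng[2L])
    stop("degenerate input: image is constant")
  integerish <- max(abs(x - round(x))) < 1e-9 && diff(rng) <= 4096
  if (integerish) {
    g <- round(x)
    lev <- seq(rng[1L], rng[2L])
    h <- tabulate(g - rng[1L] + 1L, nbins = length(lev))
    centers <- lev
    to_value <- function(i) (centers[i] + centers[i + 1L]) / 2
  } else {
    # affine map onto count-like bin indices 0..bins-1
    br <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    g <- findInterval(x, br, rightmost.closed = TRUE)
    h <- tabulate(g, nbins = bins)
    centers <- 0:(bins - 1L)
    to_value <- function(i) br[i + 1L]   # edge between bins i and i + 1
  }
  n <- sum(h)
  cs <- cumsum(h)
  csg <- cumsum(h * centers)
  k <- length(h)
  i <- seq_len(k - 1L)                       # split after bin i
  n0 <- cs[i];            n1 <- n - n0
  valid <- n0 > 0 & n1 > 0
  mu0 <- csg[i] / pmax(n0, 1)
  mu1 <- (csg[k] - csg[i]) / pmax(n1, 1)
  valid <- valid & mu1 > 0 & mu1 > mu0
  mu0 <- pmax(mu0, 1e-8)
  p0 <- n0 / n; p1 <- n1 / n
  # negative log-likelihood of the split under Poisson class models
  j <- -(n0 * log(p0) + csg[i] * log(mu0) - n0 * mu0) -
    (n1 * log(p1) + (csg[k] - csg[i]) * log(mu1) - n1 * mu1)
  j[!valid] <- Inf
  if (!any(is.finite(j))) stop("degenerate input: no valid split")
  best <- which.min(j)
  to_value(best)
}

#' Adaptive-mask generation configuration
#'
#' Parameters of the adaptive support-mask generator: the two structuring
#' elements of the open-closing / close-opening cascades, the Gaussian
#' smoothing width, which intensity class counts as object, and whether
#' the amplitude and phase masks are kept separate or unioned.
#'
#' @param se1,se2 Structuring elements `G1`, `G2`; defaults are the
#'   disk of radius 1 and the 2 x 2 square.
#' @param gaussian_sigma Gaussian smoothing sigma in pixels (>= 0).
#' @param polarity `"auto"` (object = minority class after thresholding),
#'   `"bright"` or `"dark"`.
#' @param combine_mode `"separate"` or `"union"` for the amplitude/phase
#'   mask pair.
#' @return An object of class `mask_config`.
#' @export
mask_config <- function(se1 = disk_se(1), se2 = square_se(2),
                        gaussian_sigma = 1,
                        polarity = c("auto", "bright", "dark"),
                        combine_mode = c("separate", "union")) {
  stopifnot(inherits(se1, "struct_el"), inherits(se2, "struct_el"),
            is.numeric(gaussian_sigma), gaussian_sigma >= 0)
  structure(list(se1 = se1, se2 = se2, gaussian_sigma = gaussian_sigma,
                 polarity = match.arg(polarity),
                 combine_mode = match.arg(combine_mode)),
            class = "mask_config")
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel_1d(sigma)
  x <- cpp_filter2(x, matrix(k, ncol = 1L))
  cpp_filter2(x, matrix(k, nrow = 1L))
}

sobel_magnitude <- function(x) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  gx <- cpp_filter2(x, kx)
  gy <- cpp_filter2(x, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Generate an adaptive support mask from a reconstructed image
#'
#' The mask-generation pipeline: (i) binarize at the parameter-free
#' Poisson-model threshold, resolving which class is object via
#' `cfg$polarity`; (ii) average the open-closing and close-opening
#' cascades, `(OC(B) + CO(B)) / 2`, which trades off the shrinkage of
#' open-closing against the expansion of close-opening; (iii) smooth with
#' a Gaussian of width `cfg$gaussian_sigma`; (iv) re-binarize at a
#' threshold taken from the Sobel edge map of the smoothed image (the
#' mean smoothed value over strong-edge pixels, i.e. the half-height of
#' the transition; 0.5 if no edge pixels are detected).
#'
#' A degenerate input (constant image, or a threshold that leaves no
#' object pixels) yields an all-`FALSE` mask with attribute
#' `degenerate = TRUE` and a warning; the retrieval loop then skips the
#' constraint for that iteration.
#'
#' @param x Nonnegative real matrix (e.g. a reconstructed amplitude, or a
#'   phase-deviation image).
#' @param cfg A [mask_config].
#' @return Logical mask of the same shape (attribute `degenerate` flags
#'   the fallback path).
#' @export
adaptive_mask <- function(x, cfg = mask_config()) {
  stopifnot(is.matrix(x), is.numeric(x), inherits(cfg, "mask_config"))
  if (anyNA(x) || any(!is.finite(x))) stop("image must be finite")
  degenerate <- function(msg) {
    warning(msg, call. = FALSE)
    structure(matrix(FALSE, nrow(x), ncol(x)), degenerate = TRUE)
  }
  thr <- tryCatch(poisson_threshold(x), error = function(e) NULL)
  if (is.null(thr)) return(degenerate("degenerate image; empty mask"))
  bright <- x > thr
  b <- switch(cfg$polarity,
              bright = bright,
              dark = !bright,
              auto = if (sum(bright) <= length(bright) / 2) bright
                     else !bright)
  if (!any(b)) return(degenerate("thresholding found no object pixels"))
  fbar <- (open_close(b, cfg$se1, cfg$se2) +
             close_open(b, cfg$se1, cfg$se2)) / 2
  sm <- gaussian_smooth(fbar, cfg$gaussian_sigma)
  gmag <- sobel_magnitude(sm)
  edges <- gmag > 4 * mean(gmag)
  thr2 <- if (any(edges)) mean(sm[edges]) else 0.5
  mask <- sm > thr2
  if (!any(mask)) return(degenerate("adaptive mask is empty"))
  structure(mask, degenerate = FALSE)
}

#' Object-plane constraint state from the current reconstruction
#'
#' Builds the pair of adaptive support masks used by the iteration: the
#' amplitude mask from the reconstructed amplitude image, and the phase
#' mask from the phase-deviation image `|Arg(u) - median(Arg(u))|`
#' (median-centred so that phase excursions of either sign count as
#' foreground, and a global phase constant has no effect).
#'
#' @param field The current object-plane [complex_field].
#' @param cfg A [mask_config].
#' @param background_amplitude Optional scalar; defaults to the median
#'   amplitude outside the amplitude mask (the unscattered-beam level).
#' @return An object of class `constraint_state`: list with `amp_mask`,
#'   `phase_mask`, `background_amplitude`, and degeneracy flags.
#' @export
constraint_state <- function(field, cfg = mask_config(),
                             background_amplitude = NULL) {
  stopifnot(inherits(field, "complex_field"))
  amp <- Mod(field$values)
  ph <- Arg(field$values)
  dev <- abs(ph - stats::median(ph))
  amp_mask <- adaptive_mask(amp, cfg)
  phase_cfg <- cfg
  phase_cfg$polarity <- "bright"   # deviation image: object is always high
  phase_mask <- adaptive_mask(dev, phase_cfg)
  if (cfg$combine_mode == "union") {
    u <- amp_mask | phase_mask
    attr(u, "degenerate") <- attr(amp_mask, "degenerate") &&
      attr(phase_mask, "degenerate")
    amp_mask <- phase_mask <- u
  }
  if (is.null(background_amplitude)) {
    outside <- !amp_mask
    background_amplitude <-
      if (any(outside)) stats::median(amp[outside]) else stats::median(amp)
  }
  structure(list(amp_mask = amp_mask, phase_mask = phase_mask,
                 background_amplitude = max(0, background_amplitude),
                 amp_degenerate = isTRUE(attr(amp_mask, "degenerate")),
                 phase_degenerate = isTRUE(attr(phase_mask, "degenerate"))),
            class = "constraint_state")
}

#' Apply a support constraint to an object-plane field
#'
#' Two application rules are provided.  `"background_fill"` (default)
#' models a transmitting background: outside the amplitude mask the
#' amplitude is set to `background_amplitude` and outside the phase mask
#' the phase is set to zero, so the surround reverts to the unscattered
#' plane wave.  `"hadamard"` is the literal elementwise product of each
#' component with its mask (outside-support amplitude and phase both
#' zero), the textbook support-constraint definition.
#'
#' @param field Object-plane [complex_field].
#' @param state A [constraint_state] (masks may also be a static support
#'   via [constraint_from_mask()]).
#' @param mode `"background_fill"` or `"hadamard"`.
#' @return Constrained [complex_field].
#' @export
apply_constraint <- function(field, state,
                             mode = c("background_fill", "hadamard")) {
  stopifnot(inherits(field, "complex_field"),
            inherits(state, "constraint_state"))
  mode <- match.arg(mode)
  if (!all(dim(state$amp_mask) == dim(field$values)))
    stop("mask shape does not match the field")
  v <- field$values
  amp <- Mod(v)
  ma <- state$amp_mask
  mp <- state$phase_mask
  # piecewise by mask combination, leaving untouched samples bit-exact
  if (mode == "hadamard") {
    out <- matrix(0 + 0i, nrow(v), ncol(v))
    keep <- ma & mp
    out[keep] <- v[keep]
    az <- ma & !mp                       # amplitude kept, phase zeroed
    out[az] <- amp[az]
  } else {
    bg <- state$background_amplitude
    out <- v
    az <- ma & !mp
    out[az] <- amp[az]
    pz <- !ma & mp                       # amplitude -> background
    if (any(pz)) {
      unit <- v[pz] / amp[pz]
      unit[amp[pz] == 0] <- 1 + 0i
      out[pz] <- bg * unit
    }
    out[!ma & !mp] <- bg
  }
  complex_field(out, field$pitch, field$wavelength)
}

#' Constraint state from a fixed support mask
#'
#' Wraps a static support (rectangular or circular aperture, or any
#' boolean mask) as a [constraint_state] so the same application rules
#' serve both the static baseline and the adaptive method.
#'
#' @param mask Logical matrix.
#' @param background_amplitude Scalar background amplitude for
#'   `"background_fill"` application (default 1, a unit plane wave).
#' @return A `constraint_state`.
#' @export
constraint_from_mask <- function(mask, background_amplitude = 1) {
  mask <- as_mask(mask)
  structure(list(amp_mask = mask, phase_mask = mask,
                 background_amplitude = max(0, background_amplitude),
                 amp_degenerate = FALSE, phase_degenerate = FALSE),
            class = "constraint_state")
}

#' Static aperture support masks
#'
#' The conventional fixed support: a rectangular or circular aperture on
#' the working grid.
#'
#' @param shape `c(rows, cols)` of the mask.
#' @param geometry `"rect"` or `"circle"`.
#' @param bounds For `"rect"`: `c(row1, row2, col1, col2)` (inclusive).
#' @param center,radius For `"circle"`: centre `c(row, col)` and radius in
#'   pixels (membership `(r - r0)^2 + (c - c0)^2 <= radius^2`).
#' @return Logical mask.
#' @examples
#' m <- support_mask(c(64, 64), "circle", center = c(32, 32), radius = 10)
#' @export
support_mask <- function(shape, geometry = c("rect", "circle"),
                         bounds = NULL, center = NULL, radius = NULL) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  m <- matrix(FALSE, shape[1L], shape[2L])
  if (geometry == "rect") {
    if (is.null(bounds) || length(bounds) != 4L)
      stop("`bounds` = c(row1, row2, col1, col2) required for rect")
    b <- as.integer(bounds)
    if (b[1L] < 1L || b[3L] < 1L || b[2L] > shape[1L] || b[4L] > shape[2L] ||
        b[1L] > b[2L] || b[3L] > b[4L])
      stop("rect bounds out of range")
    m[b[1L]:b[2L], b[3L]:b[4L]] <- TRUE
  } else {
    if (is.null(center) || is.null(radius))
      stop("`center` and `radius` required for circle")
    if (radius < 0) stop("radius must be nonnegative")
    if (any(center < 1) || any(center > shape))
      stop("circle centre out of range")
    rr <- (seq_len(shape[1L]) - center[1L])^2
    cc <- (seq_len(shape[2L]) - center[2L])^2
    m <- outer(rr, cc, `+`) <= radius^2
  }
  m
}

#' Jaccard index of two masks
#'
#' @param a,b Logical matrices of equal shape.
#' @return `|a & b| / |a | b|` (1 when both are empty).
#' @export
jaccard <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
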