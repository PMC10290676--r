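#' Initialize the sensor-plane field from a hologram
#'
#' The hologram is padded with a constant to the working grid (padding
#' suppresses the wraparound of the circular-convolution propagation
#' model), the initial amplitude is the square root of the padded
#' hologram, and the initial phase is zero or seeded uniform random in
#' (-pi, pi].
#'
#' @param holo A [hologram].
#' @param pad_shape Working-grid shape; default twice the hologram shape.
#' @param pad_fill `"border"` (mean of the 5-pixel border ring, matching
#'   the unscattered-beam level) or a numeric constant.
#' @param initial_phase `"zeros"` or `"random"`.
#' @param seed Seed for the random initial phase.
#' @return A [complex_field] on the padded grid, with attributes
#'   `pad_offset`/`pad_original` of the padding and `sqrt_holo`, the
#'   padded amplitude data used by the sensor update.
#' @export
init_sensor_field <- function(holo, pad_shape = 2L * dim(holo),
                              pad_fill = "border",
                              initial_phase = c("zeros", "random"),
                              seed = 1L) {
  stopifnot(inherits(holo, "hologram"))
  initial_phase <- match.arg(initial_phase)
  fill <- if (identical(pad_fill, "border")) border_mean(holo$intensity)
          else as.numeric(pad_fill)
  i0 <- pad_constant(holo$intensity, pad_shape, fill)
  sq <- sqrt(i0)
  ph <- if (initial_phase == "zeros") 0 else {
    set.seed(as.integer(seed))
    matrix(stats::runif(length(sq), -pi, pi), nrow(sq), ncol(sq))
  }
  values <- matrix(complex(modulus = as.vector(sq), argument = as.vector(ph),
                           length.out = length(sq)), nrow(sq), ncol(sq))
  out <- complex_field(values, holo$pitch, holo$wavelength)
  attr(out, "pad_offset") <- attr(i0, "pad_offset")
  attr(out, "pad_original") <- attr(i0, "pad_original")
  attr(out, "sqrt_holo") <- unclass_attr(sq)
  out
}

empty_trace <- function(rec_iter) {
  n <- length(rec_iter)
  data.frame(iteration = rec_iter, seconds = rep(NA_real_, n),
             mse_amp = rep(NA_real_, n), mse_phase = rep(NA_real_, n),
             mask_area = rep(NA_real_, n))
}

border_mean <- function(x, ring = 5L) {
  n <- nrow(x); m <- ncol(x)
  ring <- min(ring, n %/% 2L, m %/% 2L)
  idx <- matrix(FALSE, n, m)
  idx[c(seq_len(ring), n - seq_len(ring) + 1L), ] <- TRUE
  idx[, c(seq_len(ring), m - seq_len(ring) + 1L)] <- TRUE
  mean(x[idx])
}

unclass_attr <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Sensor-plane amplitude update
#'
#' Replaces the field's amplitude with the measured square-root hologram
#' while keeping the phase (zero where the field vanishes).
#'
#' @param field Sensor-plane [complex_field].
#' @param sqrt_holo Nonnegative matrix of the same shape.
#' @return Updated [complex_field].
#' @export
sensor_amplitude_update <- function(field, sqrt_holo) {
  stopifnot(inherits(field, "complex_field"))
  if (!all(dim(sqrt_holo) == dim(field$values)))
    stop("shape mismatch between field and sqrt_holo")
  ph <- Arg(field$values)          # Arg(0+0i) is 0: zero-phase convention
  values <- matrix(complex(modulus = as.vector(sqrt_holo),
                           argument = as.vector(ph),
                           length.out = length(ph)),
                   nrow(ph), ncol(ph))
  complex_field(values, field$pitch, field$wavelength)
}

#' Iterative phase retrieval from a single in-line hologram
#'
#' Gerchberg-Saxton-style iteration between the sensor and object planes.
#' Each iteration back-propagates the sensor field to the object plane,
#' applies the object-plane constraint (adaptive morphological masks
#' regenerated from the current amplitude and phase; or a fixed support;
#' or none), propagates forward, and restores the measured amplitude at
#' the sensor.  The returned reconstruction is the back-propagation of
#' the final sensor field, cropped to the original hologram extent.
#'
#' @param holo A [hologram].
#' @param z Object-to-sensor distance in metres; defaults to `holo$z`.
#' @param iterations Number of iterations (>= 0; 0 gives the plain
#'   back-propagation reconstruction).
#' @param constraint `"adaptive"`, `"support"` or `"none"`.
#' @param mask_cfg A [mask_config] (adaptive constraint).
#' @param support Logical support mask, at either the hologram extent
#'   (padded with `FALSE`) or the working-grid extent.
#' @param mode Constraint application mode, see [apply_constraint()].
#' @param pad_shape,pad_fill,initial_phase,seed See [init_sensor_field()].
#' @param mask_every Regenerate the adaptive masks every `mask_every`
#'   iterations (default 1, i.e. every iteration).
#' @param record_every Record diagnostics every this many iterations.
#' @param snapshot_every Store adaptive amplitude-mask snapshots at this
#'   stride (0 = none).
#' @param ground_truth Optional [complex_field] at the hologram extent;
#'   when supplied, per-record amplitude/phase NMSE traces are computed.
#' @param background_amplitude Background level for `"support"` /
#'   `"background_fill"`; default 1.
#' @return A `retrieval_result`: list with `object_field` (cropped
#'   [complex_field]), `trace` (data.frame: iteration, seconds, mse_amp,
#'   mse_phase, mask_area), `mask_snapshots`, and the resolved settings.
#' @examples
#' sc <- sim_scene(shape = c(64, 64), pad_shape = c(128, 128))
#' h <- forward_hologram(sc$field, z = sc$z)
#' r <- retrieve(h, iterations = 5, pad_shape = c(128, 128),
#'               ground_truth = sc$field)
#' @export
retrieve <- function(holo, z = holo$z, iterations = 100L,
                     constraint = c("adaptive", "support", "none"),
                     mask_cfg = mask_config(), support = NULL,
                     mode = c("background_fill", "hadamard"),
                     pad_shape = 2L * dim(holo), pad_fill = "border",
                     initial_phase = c("zeros", "random"), seed = 1L,
                     mask_every = 1L, record_every = 1L,
                     snapshot_every = 0L, ground_truth = NULL,
                     background_amplitude = 1) {
  stopifnot(inherits(holo, "hologram"))
  constraint <- match.arg(constraint)
  mode <- match.arg(mode)
  if (is.na(z) || z <= 0) stop("a positive distance `z` is required")
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 0L, mask_every >= 1L, record_every >= 1L)

  us <- init_sensor_field(holo, pad_shape, pad_fill, initial_phase, seed)
  sqrt_holo <- attr(us, "sqrt_holo")
  off <- attr(us, "pad_offset"); orig <- attr(us, "pad_original")
  crop <- function(m) unpad(m, orig, off)

  if (constraint == "support") {
    if (is.null(support)) stop("constraint = \"support\" needs a mask")
    support <- as_mask(support)
    if (all(dim(support) == dim(holo))) {
      support <- pad_constant(support * 1, dim(us$values), 0) > 0
    } else if (!all(dim(support) == dim(us$values)))
      stop("support mask must match the hologram or the padded grid")
    state <- constraint_from_mask(support, background_amplitude)
  }

  grid <- frequency_grid(dim(us$values), holo$pitch)
  Hb <- transfer_function(grid, -z, holo$wavelength)
  Hf <- transfer_function(grid, +z, holo$wavelength)
  npx <- length(us$values)
  prop <- function(v, H) stats::fft(stats::fft(v) * H, inverse = TRUE) / npx

  gt_amp <- gt_phase <- NULL
  if (!is.null(ground_truth)) {
    stopifnot(inherits(ground_truth, "complex_field"))
    gt_amp <- Mod(ground_truth$values)
    gt_phase <- Arg(ground_truth$values)
  }

  rec_iter <- seq_len(iterations)[seq_len(iterations) %% record_every == 0L]
  trace <- empty_trace(rec_iter)
  snapshots <- list()
  t0 <- proc.time()[["elapsed"]]
  state_cur <- NULL
  ri <- 0L

  v <- us$values
  for (k in seq_len(iterations)) {
    uo <- prop(v, Hb)                                  # object plane
    if (constraint == "adaptive" &&
        (is.null(state_cur) || (k - 1L) %% mask_every == 0L)) {
      state_cur <- suppressWarnings(constraint_state(
        complex_field(uo, holo$pitch, holo$wavelength), mask_cfg))
    } else if (constraint == "support") state_cur <- state

    uo_c <- uo
    if (constraint != "none") {
      fo <- complex_field(uo, holo$pitch, holo$wavelength)
      amp_ok <- !state_cur$amp_degenerate
      ph_ok <- !state_cur$phase_degenerate
      if (amp_ok || ph_ok) {
        st <- state_cur
        if (!amp_ok) st$amp_mask <- matrix(TRUE, nrow(uo), ncol(uo))
        if (!ph_ok) st$phase_mask <- matrix(TRUE, nrow(uo), ncol(uo))
        uo_c <- apply_constraint(fo, st, mode)$values
      }
    }
    v <- prop(uo_c, Hf)                                # sensor plane
    v <- matrix(complex(modulus = as.vector(sqrt_holo),
                        argument = as.vector(Arg(v)),
                        length.out = npx), nrow(v), ncol(v))

    if (k %% record_every == 0L) {
      ri <- ri + 1L
      trace$seconds[ri] <- proc.time()[["elapsed"]] - t0
      if (constraint == "adaptive")
        trace$mask_area[ri] <- sum(state_cur$amp_mask)
      else if (constraint == "support")
        trace$mask_area[ri] <- sum(state_cur$amp_mask)
      if (!is.null(gt_amp)) {
        est <- crop(uo)
        trace$mse_amp[ri] <- nmse(Mod(est), gt_amp)
        trace$mse_phase[ri] <- nmse_phase(Arg(est), gt_phase)
      }
      if (snapshot_every > 0L && k %% snapshot_every == 0L &&
          constraint == "adaptive")
        snapshots[[as.character(k)]] <- state_cur$amp_mask
    }
  }

  uo_final <- prop(v, Hb)
  object_field <- complex_field(crop(uo_final), holo$pitch, holo$wavelength)
  res <- structure(list(
    object_field = object_field,
    trace = trace,
    mask_snapshots = snapshots,
    final_mse_amp = if (!is.null(gt_amp))
      nmse(Mod(object_field$values), gt_amp) else NA_real_,
    final_mse_phase = if (!is.null(gt_amp))
      nmse_phase(Arg(object_field$values), gt_phase) else NA_real_,
    settings = list(method = constraint, z = z, iterations = iterations,
                    pad_shape = dim(us$values), mode = mode,
                    initial_phase = match.arg(initial_phase), seed = seed,
                    record_every = record_every)),
    class = "retrieval_result")
  res
}

#' @export
print.retrieval_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<retrieval_result> method = %s, %d iterations, z = %.4g cm\n",
              s$method, s$iterations, s$z * 100))
  if (!is.na(x$final_mse_amp))
    cat(sprintf("  final NMSE: amplitude %.4g, phase %.4g\n",
                x$final_mse_amp, x$final_mse_phase))
  invisible(x)
}

#' @export
as.data.frame.retrieval_result <- function(x, ...) {
  cbind(x$trace, method = x$settings$method)
}

#' Multi-distance phase retrieval (MPR) baseline
#'
#' Phase retrieval from several holograms recorded at different
#' object-to-sensor distances: each iteration cycles through the planes
#' nearest to farthest, propagating the current field to each plane and
#' replacing its amplitude with the measured square-root hologram while
#' keeping the phase, then returns from the last plane to the first.  No
#' object-plane mask is applied.  The readout is the back-propagation to
#' the object plane, cropped to the hologram extent.
#'
#' @param holos List of [hologram]s sharing grid, pitch and wavelength.
#' @param z_list Matching distances in metres, strictly increasing.
#' @param iterations,pad_shape,pad_fill,initial_phase,seed,record_every,ground_truth
#'   As in [retrieve()].
#' @return A `retrieval_result`.
#' @export
retrieve_mpr <- function(holos, z_list, iterations = 100L,
                         pad_shape = NULL, pad_fill = "border",
                         initial_phase = c("zeros", "random"), seed = 1L,
                         record_every = 1L, ground_truth = NULL) {
  stopifnot(is.list(holos), length(holos) >= 1L)
  if (length(holos) != length(z_list))
    stop("`holos` and `z_list` lengths differ")
  if (length(z_list) > 1L && any(diff(z_list) <= 0))
    stop("`z_list` must be strictly increasing")
  h1 <- holos[[1L]]
  stopifnot(inherits(h1, "hologram"))
  if (is.null(pad_shape)) pad_shape <- 2L * dim(h1)
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 0L)
  K <- length(holos)

  us <- init_sensor_field(h1, pad_shape, pad_fill, initial_phase, seed)
  off <- attr(us, "pad_offset"); orig <- attr(us, "pad_original")
  crop <- function(m) unpad(m, orig, off)
  sqrts <- lapply(holos, function(h) {
    stopifnot(all(dim(h) == dim(h1)))
    fill <- if (identical(pad_fill, "border")) border_mean(h$intensity)
            else as.numeric(pad_fill)
    unclass_attr(sqrt(pad_constant(h$intensity, pad_shape, fill)))
  })

  grid <- frequency_grid(dim(us$values), h1$pitch)
  npx <- length(us$values)
  prop <- function(v, H) stats::fft(stats::fft(v) * H, inverse = TRUE) / npx
  Hstep <- lapply(seq_len(K), function(k) {
    dz <- if (k == 1L) z_list[1L] - z_list[K] else z_list[k] - z_list[k - 1L]
    transfer_function(grid, dz, h1$wavelength)
  })
  Hread <- transfer_function(grid, -z_list[1L], h1$wavelength)

  gt_amp <- gt_phase <- NULL
  if (!is.null(ground_truth)) {
    gt_amp <- Mod(ground_truth$values)
    gt_phase <- Arg(ground_truth$values)
  }
  rec_iter <- seq_len(iterations)[seq_len(iterations) %% record_every == 0L]
  trace <- empty_trace(rec_iter)
  t0 <- proc.time()[["elapsed"]]
  ri <- 0L
  amp_update <- function(v, sq)
    matrix(complex(modulus = as.vector(sq), argument = as.vector(Arg(v)),
                   length.out = npx), nrow(v), ncol(v))

  v <- us$values                      # field at plane 1
  for (k in seq_len(iterations)) {
    if (K > 1L) {
      for (p in 2:K) v <- amp_update(prop(v, Hstep[[p]]), sqrts[[p]])
      v <- amp_update(prop(v, Hstep[[1L]]), sqrts[[1L]])
    } else {
      v <- amp_update(v, sqrts[[1L]])
    }
    if (k %% record_every == 0L) {
      ri <- ri + 1L
      trace$seconds[ri] <- proc.time()[["elapsed"]] - t0
      if (!is.null(gt_amp)) {
        est <- crop(prop(v, Hread))
        trace$mse_amp[ri] <- nmse(Mod(est), gt_amp)
        trace$mse_phase[ri] <- nmse_phase(Arg(est), gt_phase)
      }
    }
  }
  uo <- crop(prop(v, Hread))
  object_field <- complex_field(uo, h1$pitch, h1$wavelength)
  structure(list(
    object_field = object_field, trace = trace, mask_snapshots = list(),
    final_mse_amp = if (!is.null(gt_amp))
      nmse(Mod(object_field$values), gt_amp) else NA_real_,
    final_mse_phase = if (!is.null(gt_amp))
      nmse_phase(Arg(object_field$values), gt_phase) else NA_real_,
    settings = list(method = "mpr", z = z_list[1L], z_list = z_list,
                    iterations = iterations, pad_shape = dim(us$values),
                    mode = "none", initial_phase = match.arg(initial_phase),
                    seed = seed, record_every = record_every)),
    class = "retrieval_result")
}
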