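#' Reference-normalized mean square error
#'
#' `NMSE = sum(|est - ref|^2) / sum(|ref|^2)`, the reconstruction-quality
#' metric used throughout the package.  It is 0 iff the images agree, 1
#' for an all-zero estimate, and invariant under simultaneous scaling of
#' both images.
#'
#' @param estimate,reference Real matrices of equal shape;
#'   `sum(reference^2)` must be positive.
#' @return Scalar NMSE.
#' @examples
#' nmse(matrix(c(1, 1)), matrix(c(1, 2)))  # (0 + 1) / (1 + 4) = 0.2
#' @export
nmse <- function(estimate, reference) {
  stopifnot(is.numeric(estimate), is.numeric(reference),
            all(dim(estimate) == dim(reference)))
  denom <- sum(reference^2)
  if (denom <= 0) stop("degenerate input: reference is all zero")
  sum((estimate - reference)^2) / denom
}

#' Phase NMSE with global-piston removal
#'
#' Intensity-only retrieval is blind to a global phase offset, so before
#' computing the NMSE the mean phase difference over the reference
#' support (pixels where the reference is nonzero; all pixels if none)
#' is subtracted from the estimate, modulo 2*pi, and the result is
#' wrapped to (-pi, pi].  Set `piston = FALSE` for the raw comparison.
#'
#' @param estimate,reference Phase matrices in radians.
#' @param piston Remove the global piston first (default `TRUE`).
#' @return Scalar NMSE of the (piston-corrected) phase.
#' @export
nmse_phase <- function(estimate, reference, piston = TRUE) {
  stopifnot(all(dim(estimate) == dim(reference)))
  if (piston) {
    supp <- reference != 0
    if (!any(supp)) supp <- !logical(length(reference))
    d <- wrap_phase(estimate - reference)
    estimate <- wrap_phase(estimate - mean(d[supp]))
  }
  nmse(estimate, reference)
}

#' Compare retrieval runs against a common ground truth
#'
#' Computes per-method final metrics (amplitude/phase NMSE, amplitude
#' Pearson correlation) and collects the per-iteration NMSE curves of
#' each run into one long table for plotting or CSV export.
#'
#' @param results Named list of `retrieval_result`s on the same grid.
#' @param ground_truth A [complex_field] at the reconstruction extent.
#' @return List of class `holo_comparison`: `summary` (one row per
#'   method) and `curves` (long data.frame: method, iteration, seconds,
#'   mse_amp, mse_phase).
#' @export
compare_runs <- function(results, ground_truth) {
  stopifnot(is.list(results), length(results) >= 1L,
            inherits(ground_truth, "complex_field"))
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- vapply(results, function(r) r$settings$method,
                             character(1L))
  gt_amp <- Mod(ground_truth$values)
  gt_phase <- Arg(ground_truth$values)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    stopifnot(inherits(r, "retrieval_result"))
    if (!all(dim(r$object_field$values) == dim(gt_amp)))
      stop("result grid does not match the ground truth")
    amp <- Mod(r$object_field$values)
    data.frame(method = nm,
               mse_amp = nmse(amp, gt_amp),
               mse_phase = nmse_phase(Arg(r$object_field$values), gt_phase),
               correlation_amp = stats::cor(as.vector(amp),
                                            as.vector(gt_amp)),
               iterations = r$settings$iterations)
  })
  curves <- do.call(rbind, lapply(names(results), function(nm) {
    tr <- results[[nm]]$trace
    if (nrow(tr) == 0L) return(NULL)
    cbind(method = nm, tr[c("iteration", "seconds", "mse_amp",
                            "mse_phase")])
  }))
  structure(list(summary = do.call(rbind, rows), curves = curves),
            class = "holo_comparison")
}

#' @export
print.holo_comparison <- function(x, ...) {
  cat("<holo_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @rdname compare_runs
#' @param x A `holo_comparison`.
#' @param path Output CSV path for the per-iteration curves.
#' @export
write_curves_csv <- function(x, path) {
  stopifnot(inherits(x, "holo_comparison"))
  utils::write.csv(x$curves, path, row.names = FALSE)
  invisible(path)
}
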