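#' Plot a retrieval result
#'
#' Shows the reconstructed amplitude and phase, and the NMSE trace when
#' ground truth was supplied.
#'
#' @param x A `retrieval_result`.
#' @param ... Unused.
#' @export
plot.retrieval_result <- function(x, ...) {
  has_trace <- !all(is.na(x$trace$mse_amp))
  op <- graphics::par(mfrow = c(1L, if (has_trace) 3L else 2L),
                      mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  show_img(Mod(x$object_field$values), "amplitude")
  show_img(Arg(x$object_field$values), "phase (rad)")
  if (has_trace) {
    graphics::plot(x$trace$iteration, x$trace$mse_amp, type = "l",
                   log = "y", xlab = "iteration", ylab = "NMSE",
                   main = "convergence")
    graphics::lines(x$trace$iteration, x$trace$mse_phase, lty = 2)
    graphics::legend("topright", c("amplitude", "phase"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Plot method comparison curves
#'
#' NMSE-versus-iteration curves for every method in the comparison, on a
#' log scale.
#'
#' @param x A `holo_comparison` from [compare_runs()].
#' @param which `"amp"` or `"phase"`.
#' @param ... Unused.
#' @export
plot.holo_comparison <- function(x, which = c("amp", "phase"), ...) {
  which <- match.arg(which)
  col_name <- paste0("mse_", which)
  cur <- x$curves[!is.na(x$curves[[col_name]]), ]
  methods <- unique(cur$method)
  cols <- seq_along(methods)
  graphics::plot(range(cur$iteration), range(cur[[col_name]]),
                 type = "n", log = "y", xlab = "iteration",
                 ylab = sprintf("NMSE (%s)", which))
  for (i in seq_along(methods)) {
    m <- cur[cur$method == methods[i], ]
    graphics::lines(m$iteration, m[[col_name]], col = cols[i])
  }
  graphics::legend("topright", methods, col = cols, lty = 1, bty = "n")
  invisible(x)
}

show_img <- function(m, main) {
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE,
                  col = grDevices::gray.colors(256), main = main,
                  useRaster = TRUE)
}
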