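#' Structuring elements
#'
#' A structuring element (SE) is a small binary neighborhood with an
#' origin; it is the probe of the binary morphological operations.
#' `disk_se(radius)` gives the digital disk `{(r, c): r^2 + c^2 <=
#' radius^2}` centred on its origin (radius 1 is the 5-cell plus shape,
#' radius 0 a single cell).  `square_se(n)` gives an `n x n` all-true
#' footprint; an odd square is centred on its middle cell while an even
#' square, which has no centre, keeps its origin at the top-left cell.
#'
#' @param footprint Logical matrix with at least one `TRUE` cell.
#' @param origin `c(row, col)` index of the origin within the footprint
#'   (1-based).
#' @return An object of class `struct_el`.
#' @examples
#' disk_se(1)    # plus-shaped, 5 cells
#' square_se(2)  # 2 x 2, origin top-left
#' @export
struct_el <- function(footprint, origin) {
  stopifnot(is.matrix(footprint), is.logical(footprint))
  if (!any(footprint)) stop("structuring element must have a true cell")
  origin <- as.integer(origin)
  if (length(origin) != 2L || any(origin < 1L) || any(origin > dim(footprint)))
    stop("origin must lie inside the footprint")
  structure(list(footprint = footprint, origin = origin),
            class = "struct_el")
}

#' @rdname struct_el
#' @param radius Disk radius in pixels (integer >= 0).
#' @export
disk_se <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("`radius` must be a nonnegative number")
  radius <- as.integer(radius)
  n <- 2L * radius + 1L
  d <- seq(-radius, radius)
  fp <- outer(d^2, d^2, `+`) <= radius^2
  struct_el(fp, c(radius + 1L, radius + 1L))
}

#' @rdname struct_el
#' @param n Side length of the square SE (integer >= 1).
#' @export
square_se <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer")
  n <- as.integer(n)
  origin <- if (n %% 2L == 1L) c((n + 1L) %/% 2L, (n + 1L) %/% 2L)
            else c(1L, 1L)
  struct_el(matrix(TRUE, n, n), origin)
}

#' @export
print.struct_el <- function(x, ...) {
  cat(sprintf("<struct_el> %d x %d footprint, %d cells, origin (%d, %d)\n",
              nrow(x$footprint), ncol(x$footprint), sum(x$footprint),
              x$origin[1L], x$origin[2L]))
  invisible(x)
}

se_offsets <- function(se) {
  idx <- which(se$footprint, arr.ind = TRUE)
  list(dr = as.integer(idx[, 1L] - se$origin[1L]),
       dc = as.integer(idx[, 2L] - se$origin[2L]))
}

as_mask <- function(x) {
  stopifnot(is.matrix(x))
  if (!is.logical(x)) {
    if (!all(x %in% c(0, 1))) stop("mask must be boolean")
    x <- x > 0
  }
  x
}

#' Binary erosion and dilation
#'
#' Set-theoretic binary morphology.  Erosion keeps a pixel when the
#' structuring element translated to it fits entirely inside the
#' foreground (the neighborhood local minimum); dilation marks a pixel
#' when the reflected element translated to it meets the foreground (the
#' local maximum).  Samples outside the image are background (`FALSE`)
#' for both operations.
#'
#' @param f Logical matrix (foreground = `TRUE`).
#' @param se A [struct_el].
#' @return Logical matrix of the same shape.
#' @examples
#' m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
#' sum(dilate(m, disk_se(1)))  # 5-pixel plus
#' @export
erode <- function(f, se) {
  f <- as_mask(f)
  stopifnot(inherits(se, "struct_el"))
  o <- se_offsets(se)
  cpp_erode(f, o$dr, o$dc)
}

#' @rdname erode
#' @export
dilate <- function(f, se) {
  f <- as_mask(f)
  stopifnot(inherits(se, "struct_el"))
  o <- se_offsets(se)
  cpp_dilate(f, o$dr, o$dc)
}

#' Opening, closing and their cascades
#'
#' Opening (`erode` then `dilate`) removes foreground speckle smaller than
#' the SE; closing (`dilate` then `erode`) fills comparable holes.  Since
#' the two are not mutually inverse they are cascaded with two elements:
#' the open-closing `OC(F) = (F o G1) . G2` and close-opening
#' `CO(F) = (F . G1) o G2` (`o` = opening, `.` = closing).
#'
#' @param f Logical matrix.
#' @param se,se1,se2 Structuring elements.
#' @return Logical matrix.
#' @export
mopen <- function(f, se) dilate(erode(f, se), se)

#' @rdname mopen
#' @export
mclose <- function(f, se) erode(dilate(f, se), se)

#' @rdname mopen
#' @export
open_close <- function(f, se1, se2) mclose(mopen(f, se1), se2)

#' @rdname mopen
#' @export
close_open <- function(f, se1, se2) mopen(mclose(f, se1), se2)
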