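#' 3-D scalar volume with voxel spacing
#'
#' Light container for an MR-like image: a 3-D numeric array plus the voxel
#' spacing in millimetres. All geometry-aware operations in the package
#' (volumes in mm^3, lengths in mm) read the spacing from this object. Axis 3
#' (`k`) is the slice axis; "consecutive slices" always means adjacent `k`
#' indices. Voxel coordinates are 0-based `(i, j, k)` triples throughout.
#'
#' @param data numeric 3-D array of intensities (arbitrary units).
#' @param spacing numeric length-3 vector `(dx, dy, dz)` in mm, all > 0.
#' @param origin numeric length-3 mm offset, informational only.
#' @return An object of class `volume3d`: a list with elements `data`,
#'   `spacing`, `origin`.
#' @examples
#' v <- volume3d(array(rnorm(8 * 8 * 4), dim = c(8, 8, 4)),
#'               spacing = c(0.31, 0.31, 1))
#' voxel_volume(v)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3-D array, got %s dimension(s)",
          length(dim(data)) %||% "no")
  if (!all(is.finite(data)))
    stopf("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("'spacing' must be 3 positive finite numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname volume3d
#' @param volume a `volume3d` object.
#' @export
voxel_volume <- function(volume) {
  stopifnot(inherits(volume, "volume3d"))
  prod(volume$spacing)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

as_mask <- function(x, dims = NULL, what = "mask") {
  if (inherits(x, "volume3d")) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L)
    stopf("'%s' must be a 3-D array", what)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1)))
      stopf("'%s' must be binary (0/1 or logical)", what)
    x <- array(x > 0, dim = dim(x))
  }
  if (!is.logical(x)) stopf("'%s' must be binary (0/1 or logical)", what)
  if (!is.null(dims) && !identical(dim(x), as.integer(dims)))
    stopf("'%s' shape (%s) does not match volume shape (%s)", what,
          paste(dim(x), collapse = "x"), paste(dims, collapse = "x"))
  x
}

#' Region-of-interest point set
#'
#' A labelled set of 0-based voxel coordinates, used to mark the reference
#' points sampled in the sternocleidomastoid muscle (SCM).
#'
#' @param points integer matrix with 3 columns (or list of length-3 vectors):
#'   0-based `(i, j, k)` voxel coordinates.
#' @param label character label, e.g. `"SCM"`.
#' @param grid_shape optional integer length-3; when supplied every point is
#'   validated to lie inside the grid.
#' @return An object of class `roi_points`.
#' @export
roi_points <- function(points, label = "SCM", grid_shape = NULL) {
  if (is.list(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) < 1L) stopf("ROI must contain at least one point")
  if (ncol(points) != 3L) stopf("ROI points must be (i, j, k) triples")
  if (any(points != round(points)))
    stopf("ROI coordinates must be integers (0-based voxel indices)")
  storage.mode(points) <- "integer"
  if (any(points < 0L)) stopf("ROI coordinates must be >= 0 (0-based)")
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    bad <- points[, 1] >= grid_shape[1] | points[, 2] >= grid_shape[2] |
      points[, 3] >= grid_shape[3]
    if (any(bad))
      stopf("%d ROI point(s) outside grid %s", sum(bad),
            paste(grid_shape, collapse = "x"))
  }
  structure(list(points = points, label = as.character(label)),
            class = "roi_points")
}

#' @export
print.roi_points <- function(x, ...) {
  cat(sprintf("<roi_points> '%s', %d point(s)\n", x$label, nrow(x$points)))
  invisible(x)
}

# linear (1-based) array indices of 0-based (i,j,k) rows
roi_linear_index <- function(roi, dims) {
  p <- roi$points
  if (any(p[, 1] >= dims[1] | p[, 2] >= dims[2] | p[, 3] >= dims[3]))
    stopf("ROI point outside grid %s", paste(dims, collapse = "x"))
  1L + p[, 1] + dims[1] * (p[, 2] + dims[2] * p[, 3])
}
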