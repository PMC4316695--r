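#' Voxel grid geometry
#'
#' All volumes handled by dvfqa live on a regular, axis-aligned voxel lattice
#' described by a `grid_geometry`: integer dimensions, positive per-axis
#' spacing in millimetres, and a world origin in millimetres. The origin is
#' the world coordinate of the centre of the first voxel (index `(1, 1, 1)`),
#' so voxel `(i, j, k)` is centred at `origin + (c(i, j, k) - 1) * spacing`.
#' Oblique grids (non-identity direction cosines) are not supported; every
#' voxel-wise operation in the package presumes the lattice is aligned with
#' the world axes.
#'
#' @param dims Integer vector of length 3, voxels per axis; each `>= 2`.
#' @param spacing Numeric vector of length 3, mm per voxel; each `> 0`.
#' @param origin Numeric vector of length 3, mm; world position of the first
#'   voxel centre.
#'
#' @return An object of class `grid_geometry` with fields `dims`, `spacing`
#'   and `origin`.
#' @examples
#' geom <- grid_geometry(c(64, 64, 48), c(1.5, 1.5, 2.5))
#' voxel_volume(geom)
#' @export
grid_geometry <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || anyNA(dims)) {
    stop("`dims` must be three integers", call. = FALSE)
  }
  if (any(dims < 2L)) {
    stop("all grid dimensions must be >= 2 voxels", call. = FALSE)
  }
  if (length(spacing) != 3L || anyNA(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  structure(
    list(dims = dims, spacing = spacing, origin = origin),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "<grid_geometry> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
    x$dims[1], x$dims[2], x$dims[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param geom A [grid_geometry()].
#' @return Voxel volume in mm^3 (`prod(spacing)`).
#' @export
voxel_volume <- function(geom) {
  stopifnot(inherits(geom, "grid_geometry"))
  prod(geom$spacing)
}

#' Assert two grids are compatible
#'
#' Voxel-by-voxel operations (field subtraction, mask lookups, structure
#' sampling) are undefined across mismatched lattices; this guard is applied
#' by every such operation. Dimensions must match exactly; spacing and origin
#' must agree within `tol` per component, absorbing float header round-off.
#'
#' @param a,b [grid_geometry()] objects.
#' @param tol Per-component tolerance in mm for spacing and origin.
#' @return Invisibly `TRUE` on success; errors on mismatch.
#' @export
assert_same_grid <- function(a, b, tol = 1e-3) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  if (!identical(a$dims, b$dims)) {
    stop(sprintf(
      "grid mismatch: dims (%s) vs (%s)",
      paste(a$dims, collapse = ","), paste(b$dims, collapse = ",")
    ), call. = FALSE)
  }
  if (any(abs(a$spacing - b$spacing) > tol)) {
    stop("grid mismatch: voxel spacings differ beyond tolerance", call. = FALSE)
  }
  if (any(abs(a$origin - b$origin) > tol)) {
    stop("grid mismatch: origins differ beyond tolerance", call. = FALSE)
  }
  invisible(TRUE)
}

#' World coordinates of voxel centres along one axis
#' @noRd
axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$dims[axis]) - 1) * geom$spacing[axis]
}

#' Voxel-centre coordinate arrays
#'
#' Returns the world coordinates (mm) of every voxel centre as three arrays
#' of the grid's dimensions, one per axis.
#' @noRd
coord_arrays <- function(geom) {
  nx <- geom$dims[1]; ny <- geom$dims[2]; nz <- geom$dims[3]
  list(
    x = array(rep(axis_coords(geom, 1), times = ny * nz), dim = geom$dims),
    y = array(rep(rep(axis_coords(geom, 2), each = nx), times = nz), dim = geom$dims),
    z = array(rep(axis_coords(geom, 3), each = nx * ny), dim = geom$dims)
  )
}

same_geometry <- function(a, b, tol = 1e-3) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}
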