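#' Dense displacement field on a voxel grid
#'
#' A displacement vector field (DVF) stores one 3-vector per voxel, in
#' millimetres, in world axes. The transformation it encodes is
#' `T(x) = x + u(x)`. Components are ordered `(x, y, z)` along the fourth
#' array dimension, matching `(column, row, slice)` of the lattice.
#'
#' @param geometry A [grid_geometry()].
#' @param vectors Numeric array of dimension `c(dims, 3)`, mm.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(geometry, vectors) {
  stopifnot(inherits(geometry, "grid_geometry"))
  vectors <- as_numeric_array(vectors)
  if (length(dim(vectors)) != 4L || !identical(dim(vectors)[1:3], geometry$dims) ||
      dim(vectors)[4] != 3L) {
    stop("`vectors` must be an array of dimension c(dims, 3)", call. = FALSE)
  }
  if (!all(is.finite(vectors))) {
    stop("displacement components must all be finite", call. = FALSE)
  }
  structure(list(geometry = geometry, vectors = vectors),
            class = "displacement_field")
}

#' Per-voxel scalar volume
#'
#' Container for voxel-wise scalars such as Jacobian-determinant maps or
#' spatial-discrepancy maps. The `units` attribute is informational ("" for
#' dimensionless Jacobians, "cm" for spatial discrepancy).
#'
#' @param geometry A [grid_geometry()].
#' @param values Numeric array matching the grid dimensions.
#' @param units Unit label carried through to histograms and plots.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(geometry, values, units = "") {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as_numeric_array(values)
  if (!identical(dim(values), geometry$dims)) {
    stop("`values` must match the grid dimensions", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("scalar values must all be finite", call. = FALSE)
  }
  structure(list(geometry = geometry, values = values, units = units),
            class = "scalar_volume")
}

#' Binary structure mask
#'
#' Voxelized occupancy bitmap for one contoured structure (a lung, heart,
#' GTV, ...). Occupancy is strictly binary; any numeric input is binarized
#' with the `> 0.5` rule so float-stored masks with interpolation residue
#' load cleanly.
#'
#' @param geometry A [grid_geometry()].
#' @param occupancy Logical or numeric array matching the grid dimensions.
#' @param label Structure name, e.g. `"left_lung"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(geometry, occupancy, label = "structure") {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (is.null(dim(occupancy)) || !identical(as.integer(dim(occupancy)), geometry$dims)) {
    stop("`occupancy` must match the grid dimensions", call. = FALSE)
  }
  if (is.logical(occupancy)) {
    occ <- occupancy
    occ[is.na(occ)] <- FALSE
  } else {
    if (!all(is.finite(occupancy))) {
      stop("mask values must be finite", call. = FALSE)
    }
    occ <- occupancy > 0.5
  }
  dim(occ) <- geometry$dims
  structure(list(geometry = geometry, occupancy = occ, label = as.character(label)),
            class = "structure_mask")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<displacement_field> on %d x %d x %d grid, |u| in [%.3g, %.3g] mm\n",
              x$geometry$dims[1], x$geometry$dims[2], x$geometry$dims[3],
              min(mag), max(mag)))
  invisible(x)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume%s> on %d x %d x %d grid, range [%.4g, %.4g]\n",
              if (nzchar(x$units)) paste0(", ", x$units) else "",
              x$geometry$dims[1], x$geometry$dims[2], x$geometry$dims[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels set (%.4g mm^3)\n",
              x$label, sum(x$occupancy), mask_volume(x)))
  invisible(x)
}

#' Total volume of a mask
#'
#' @param mask A [structure_mask()].
#' @return Set-voxel count times voxel volume, mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy) * voxel_volume(mask$geometry)
}

as_numeric_array <- function(x) {
  if (is.null(dim(x))) stop("expected an array", call. = FALSE)
  if (!is.double(x)) {
    d <- dim(x)
    x <- as.double(x)
    dim(x) <- d
  }
  x
}
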