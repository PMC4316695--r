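#' Rasterize per-slice closed contours into a structure mask
#'
#' Planar segmentation contours — the form in which organs are usually
#' delineated — are converted into a volume bitmap: a voxel is set iff its
#' centre lies inside the polygon(s) on its slice under the even-odd rule.
#' The rule is orientation-free (clockwise and counterclockwise traversals
#' rasterize identically) and, applied across several polygons on one slice,
#' carves holes (a contour inside a contour unsets the interior). Edge
#' handling is half-open (a centre exactly on a left/bottom edge counts as
#' inside, on a right/top edge as outside) so adjacent polygons tile without
#' double-counting.
#'
#' @param contours List of contour records, each a list with `slice` (integer
#'   slice index, 1-based) and `vertices` (n x 2 matrix of in-plane world
#'   coordinates, mm; closure is implicit). At least 3 distinct vertices per
#'   contour.
#' @param geom A [grid_geometry()].
#' @param label Structure name.
#' @return A [structure_mask()].
#' @export
rasterize_contours <- function(contours, geom, label = "structure") {
  if (length(contours) == 0) stop("no contours supplied", call. = FALSE)
  occ <- array(FALSE, dim = geom$dims)
  xs <- axis_coords(geom, 1)
  ys <- axis_coords(geom, 2)
  grid_xy <- cbind(rep(xs, times = geom$dims[2]), rep(ys, each = geom$dims[1]))
  for (ct in contours) {
    slice <- as.integer(ct$slice)
    if (is.na(slice) || slice < 1L || slice > geom$dims[3]) {
      stop("contour slice index outside the grid", call. = FALSE)
    }
    v <- as.matrix(ct$vertices)
    if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    if (nrow(unique(v)) < 3) {
      stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
    }
    inside <- point_in_polygon(grid_xy[, 1], grid_xy[, 2], v[, 1], v[, 2])
    occ[, , slice] <- xor(occ[, , slice], matrix(inside, geom$dims[1], geom$dims[2]))
  }
  structure_mask(geom, occ, label = label)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# The strict/non-strict asymmetry in the comparisons yields half-open edge
# handling consistent across shared edges.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Propagate a structure mask through a displacement field
#'
#' Pull-back resampling with nearest-neighbour interpolation: each output
#' voxel centre `x` looks up the input mask at `T(x) = x + u(x)`; lookups
#' falling outside the grid yield background (0), so structures carried out
#' of the field of view vanish rather than clamp. With a field mapping the
#' target image to the moving image, this propagates a moving-image
#' segmentation onto the target grid. Note the pull-back convention: a field
#' of constant displacement `+d` shifts the mask by `-d` on the output grid.
#'
#' @param mask A [structure_mask()].
#' @param field A [displacement_field()] on the same grid.
#' @return The propagated [structure_mask()].
#' @export
warp_mask <- function(mask, field) {
  stopifnot(inherits(mask, "structure_mask"), inherits(field, "displacement_field"))
  geom <- mask$geometry
  assert_same_grid(geom, field$geometry)
  co <- coord_arrays(geom)
  ix <- as.integer(round((co$x + field$vectors[, , , 1] - geom$origin[1]) / geom$spacing[1])) + 1L
  iy <- as.integer(round((co$y + field$vectors[, , , 2] - geom$origin[2]) / geom$spacing[2])) + 1L
  iz <- as.integer(round((co$z + field$vectors[, , , 3] - geom$origin[3]) / geom$spacing[3])) + 1L
  valid <- ix >= 1L & ix <= geom$dims[1] &
    iy >= 1L & iy <= geom$dims[2] &
    iz >= 1L & iz <= geom$dims[3]
  occ <- array(FALSE, dim = geom$dims)
  lin <- ix[valid] +
    (iy[valid] - 1L) * geom$dims[1] +
    (iz[valid] - 1L) * geom$dims[1] * geom$dims[2]
  occ[valid] <- mask$occupancy[lin]
  structure_mask(geom, occ, label = mask$label)
}

#' DICE similarity coefficient between two masks
#'
#' `DICE = 2 |A intersect B| / (|A| + |B|)` by voxel counting: 1 when the
#' volumes match perfectly, 0 when they do not overlap at all. The standard
#' figure of merit for contour propagation.
#'
#' @param a,b Non-empty [structure_mask()] objects on the same grid.
#' @return DICE coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  assert_same_grid(a$geometry, b$geometry)
  na <- sum(a$occupancy); nb <- sum(b$occupancy)
  if (na + nb == 0) stop("DICE undefined: both masks are empty", call. = FALSE)
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}

#' Sample a scalar volume over a structure
#'
#' Projects a voxel-wise map (Jacobian, spatial discrepancy) onto a structure
#' bitmap: one `(value, weight)` pair per set voxel, with the value sampled
#' at the voxel centre and the weight equal to the full voxel volume in mm^3.
#' Map and mask share a grid, so centre sampling is an exact lookup. The
#' result is the substrate of all volume-histogram statistics
#' ([weighted_mean()], [weighted_std()], [tail_boundary()],
#' [build_histogram()]).
#'
#' @param scalar A [scalar_volume()].
#' @param mask A non-empty [structure_mask()] on the same grid.
#' @return A `structure_samples` tibble with columns `value` and `weight`
#'   (mm^3), and attributes `total_volume` (mm^3), `label` and `units`.
#' @export
sample_structure <- function(scalar, mask) {
  stopifnot(inherits(scalar, "scalar_volume"), inherits(mask, "structure_mask"))
  assert_same_grid(scalar$geometry, mask$geometry)
  n_set <- sum(mask$occupancy)
  if (n_set == 0) stop("empty mask", call. = FALSE)
  vv <- voxel_volume(mask$geometry)
  out <- tibble::tibble(
    value = as.vector(scalar$values[mask$occupancy]),
    weight = rep(vv, n_set)
  )
  attr(out, "total_volume") <- n_set * vv
  attr(out, "label") <- mask$label
  attr(out, "units") <- scalar$units
  class(out) <- c("structure_samples", class(out))
  out
}

#' Construct structure samples directly
#'
#' Low-level constructor used by the histogram layer and the test suite; most
#' users get samples from [sample_structure()].
#'
#' @param value Sample values.
#' @param weight Per-sample volume weights, mm^3; all `> 0`.
#' @param label Structure name.
#' @param units Value units.
#' @return A `structure_samples` tibble.
#' @export
structure_samples <- function(value, weight, label = "structure", units = "") {
  if (length(value) == 0) stop("empty samples", call. = FALSE)
  if (length(weight) != length(value)) stop("value/weight length mismatch", call. = FALSE)
  if (!all(is.finite(value)) || !all(is.finite(weight)) || any(weight <= 0)) {
    stop("values must be finite and weights positive", call. = FALSE)
  }
  out <- tibble::tibble(value = as.numeric(value), weight = as.numeric(weight))
  attr(out, "total_volume") <- sum(weight)
  attr(out, "label") <- label
  attr(out, "units") <- units
  class(out) <- c("structure_samples", class(out))
  out
}
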