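#' Jacobian-determinant map of a displacement field
#'
#' For the transformation `T(x) = x + u(x)` the local volume-change factor at
#' a voxel is `J = det(I + G)` where `G[c, d] = d u_c / d x_d` is the
#' displacement gradient — the identity matrix added to the gradient of the
#' displacement. `G` is estimated over the immediate one-voxel neighbourhood
#' with central differences, normalized by the physical spacing per axis so
#' anisotropic grids are handled correctly:
#' `G[c, d] = (u_c(i + e_d) - u_c(i - e_d)) / (2 * spacing_d)`.
#'
#' The one-voxel-wide boundary shell, where no central difference exists, is
#' set to exactly 1 (unity: no volume change). The determinant is kept
#' *signed*: `J > 1` means local expansion, `0 < J < 1` contraction, and
#' `J <= 0` a physically impossible folding of space — the sign is the
#' diagnostic, so no absolute value is taken.
#'
#' @param field A [displacement_field()].
#' @return A dimensionless [scalar_volume()] (the Jacobian map).
#' @examples
#' j <- jacobian_map(make_affine_field(diag(3) * 0.1))
#' range(j$values[2:63, 2:63, 2:47])  # 1.331, exactly: FD is exact on linear fields
#' @export
jacobian_map <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  geom <- field$geometry
  n <- geom$dims
  if (any(n < 3L)) {
    stop("grid must be at least 3 voxels per axis to have an interior",
         call. = FALSE)
  }
  u <- field$vectors
  ix <- 2:(n[1] - 1); iy <- 2:(n[2] - 1); iz <- 2:(n[3] - 1)
  g <- vector("list", 9)
  dim(g) <- c(3, 3)
  for (comp in 1:3) {
    uc <- u[, , , comp]
    g[[comp, 1]] <- (uc[ix + 1, iy, iz] - uc[ix - 1, iy, iz]) / (2 * geom$spacing[1])
    g[[comp, 2]] <- (uc[ix, iy + 1, iz] - uc[ix, iy - 1, iz]) / (2 * geom$spacing[2])
    g[[comp, 3]] <- (uc[ix, iy, iz + 1] - uc[ix, iy, iz - 1]) / (2 * geom$spacing[3])
  }
  a11 <- 1 + g[[1, 1]]; a12 <- g[[1, 2]]; a13 <- g[[1, 3]]
  a21 <- g[[2, 1]]; a22 <- 1 + g[[2, 2]]; a23 <- g[[2, 3]]
  a31 <- g[[3, 1]]; a32 <- g[[3, 2]]; a33 <- 1 + g[[3, 3]]
  det_int <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  vals <- array(1, dim = n)
  vals[ix, iy, iz] <- det_int
  scalar_volume(geom, vals, units = "")
}

#' Spatial-discrepancy map between two displacement fields
#'
#' The voxel-wise Euclidean length of the vector difference between two DVFs
#' computed on the same anatomy: `SD(i) = |u_A(i) - u_B(i)|`. Reported in
#' centimetres (internal storage is mm; clinically notable disagreements are
#' on the cm scale). Symmetric in its arguments and zero exactly where the
#' fields agree.
#'
#' @param field_a,field_b [displacement_field()] objects on the same grid.
#' @param tol Grid-compatibility tolerance, mm (see [assert_same_grid()]).
#' @return A [scalar_volume()] with `units = "cm"`.
#' @export
sd_map <- function(field_a, field_b, tol = 1e-3) {
  stopifnot(inherits(field_a, "displacement_field"),
            inherits(field_b, "displacement_field"))
  assert_same_grid(field_a$geometry, field_b$geometry, tol = tol)
  d <- field_a$vectors - field_b$vectors
  vals <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2) / 10
  scalar_volume(field_a$geometry, vals, units = "cm")
}

#' Fraction of structure volume below a scalar threshold
#'
#' Screening helper for unphysical Jacobians: with `threshold = 0` it is the
#' folded (negative-Jacobian) volume fraction; the factor-of-two physicality
#' screen uses `fraction_below(j, mask, 0.5)` for extreme compression and
#' `1 - fraction_below(j, mask, 2)` for extreme expansion.
#'
#' @param scalar A [scalar_volume()] (typically a Jacobian map).
#' @param mask A non-empty [structure_mask()] on the same grid.
#' @param threshold Threshold in the volume's units.
#' @return Fraction in `[0, 1]` of in-mask voxels with value strictly below
#'   `threshold`.
#' @export
fraction_below <- function(scalar, mask, threshold) {
  stopifnot(inherits(scalar, "scalar_volume"), inherits(mask, "structure_mask"))
  assert_same_grid(scalar$geometry, mask$geometry)
  n_set <- sum(mask$occupancy)
  if (n_set == 0) stop("empty mask", call. = FALSE)
  sum(scalar$values[mask$occupancy] < threshold) / n_set
}
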