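#' Default phantom grid
#'
#' A deliberately anisotropic desk-scale lattice (64 x 64 x 48 voxels at
#' 1.5 x 1.5 x 2.5 mm) used by the synthetic cohort and throughout the test
#' suite. The anisotropy is intentional: spacing bugs in derivative code are
#' invisible on isotropic grids.
#'
#' @return A [grid_geometry()].
#' @export
default_grid <- function() {
  grid_geometry(c(64, 64, 48), c(1.5, 1.5, 2.5), c(0, 0, 0))
}

#' Affine synthetic displacement field
#'
#' Builds `u(x) = A (x - x_c) + t` with `x_c` the grid centre in mm. The
#' displacement gradient is the constant matrix `A`, so the Jacobian
#' determinant is `det(I + A)` everywhere — an exact oracle for derivative
#' code, since central differences are exact on linear fields.
#'
#' @param A 3 x 3 displacement-gradient matrix (dimensionless).
#' @param t Translation, mm.
#' @param geom A [grid_geometry()].
#' @return A [displacement_field()] carrying a `jacobian_fn` attribute:
#'   `function(x, y, z)` in world mm returning the closed-form Jacobian.
#' @examples
#' f <- make_affine_field(diag(3) * 0.1, geom = default_grid())
#' attr(f, "jacobian_fn")(0, 0, 0)  # 1.1^3 = 1.331
#' @export
make_affine_field <- function(A, t = c(0, 0, 0), geom = default_grid()) {
  A <- matrix(as.numeric(A), 3, 3)
  t <- as.numeric(t)
  if (!all(is.finite(A)) || !all(is.finite(t)) || length(t) != 3L) {
    stop("affine parameters must be finite (3x3 matrix and length-3 translation)",
         call. = FALSE)
  }
  xc <- geom$origin + (geom$dims - 1) * geom$spacing / 2
  co <- coord_arrays(geom)
  dx <- co$x - xc[1]; dy <- co$y - xc[2]; dz <- co$z - xc[3]
  u <- array(0, dim = c(geom$dims, 3))
  for (c_i in 1:3) {
    u[, , , c_i] <- A[c_i, 1] * dx + A[c_i, 2] * dy + A[c_i, 3] * dz + t[c_i]
  }
  field <- displacement_field(geom, u)
  detIA <- det(diag(3) + A)
  attr(field, "jacobian_fn") <- function(x, y, z) rep(detIA, length(x))
  field
}

#' Axial sinusoid synthetic displacement field
#'
#' Displacement only along one axis, `u_axis(x) = a * sin(k * x_axis + phase)`
#' with `x_axis` the world coordinate (mm) along that axis. The closed-form
#' Jacobian is `1 + a*k*cos(k*x_axis + phase)`. This mimics diaphragm-like
#' nonuniform compression: most of the volume barely moves while a band is
#' compressed or stretched. Requires `|a*k| < 1` so the map never folds.
#'
#' @param a Amplitude, mm.
#' @param k Wavenumber, 1/mm.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param geom A [grid_geometry()].
#' @param phase Phase offset, radians.
#' @return A [displacement_field()] with a `jacobian_fn` attribute.
#' @export
make_axial_sinusoid_field <- function(a, k, axis = c("z", "x", "y"),
                                      geom = default_grid(), phase = 0) {
  axis <- match.arg(axis)
  if (!is.finite(a) || !is.finite(k) || !is.finite(phase)) {
    stop("sinusoid parameters must be finite", call. = FALSE)
  }
  if (abs(a * k) >= 1) {
    stop("|a*k| must be < 1: the sinusoid would fold (non-positive Jacobian)",
         call. = FALSE)
  }
  ax <- match(axis, c("x", "y", "z"))
  co <- coord_arrays(geom)[[ax]]
  u <- array(0, dim = c(geom$dims, 3))
  u[, , , ax] <- a * sin(k * co + phase)
  field <- displacement_field(geom, u)
  attr(field, "jacobian_fn") <- function(x, y, z) {
    w <- list(x, y, z)[[ax]]
    1 + a * k * cos(k * w + phase)
  }
  field
}

#' Spherical phantom structure mask
#'
#' A voxel is set iff its centre lies within `radius` of `center`. Phantom
#' stand-in for contoured organs (lungs, heart, GTV).
#'
#' @param center World centre, mm.
#' @param radius Radius, mm; must exceed the largest voxel spacing.
#' @param geom A [grid_geometry()].
#' @param label Structure name.
#' @return A non-empty [structure_mask()]; errors if the sphere misses the grid.
#' @export
make_sphere_mask <- function(center, radius, geom = default_grid(),
                             label = "sphere") {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center))) {
    stop("`center` must be three finite mm coordinates", call. = FALSE)
  }
  if (!is.finite(radius) || radius <= max(geom$spacing)) {
    stop("`radius` must exceed the largest voxel spacing", call. = FALSE)
  }
  co <- coord_arrays(geom)
  occ <- (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2 <=
    radius^2
  if (!any(occ)) {
    stop("empty mask: sphere does not intersect the grid", call. = FALSE)
  }
  structure_mask(geom, occ, label = label)
}

#' Inject a folding defect into a displacement field
#'
#' Adds a compactly supported radial inversion bump
#' `u_fold(x) = -strength * w(r) * (x - center)` with
#' `w(r) = (1 - (r/radius)^2)^2` inside the ball and exactly zero outside, so
#' voxels beyond `radius` keep their vectors bit-exactly. At the ball centre
#' the displacement gradient is `-strength * I`, giving a closed-form Jacobian
#' `(1 - strength)^3` there: any `strength > 1` forces a negative Jacobian —
#' the canonical physically impossible "folding" defect that Jacobian QA is
#' meant to catch.
#'
#' @param field A [displacement_field()].
#' @param center Ball centre, mm.
#' @param radius Ball radius, mm; must span at least 3 voxels on every axis.
#' @param strength Dimensionless inversion strength; `> 1` folds.
#' @return The modified [displacement_field()] with attribute
#'   `fold_center_jacobian` = `(1 - strength)^3`.
#' @export
inject_fold <- function(field, center, radius, strength) {
  stopifnot(inherits(field, "displacement_field"))
  geom <- field$geometry
  center <- as.numeric(center)
  if (!is.finite(radius) || radius < 3 * max(geom$spacing)) {
    stop("`radius` must span at least 3 voxels on every axis", call. = FALSE)
  }
  lo <- geom$origin
  hi <- geom$origin + (geom$dims - 1) * geom$spacing
  if (any(center < lo) || any(center > hi)) {
    stop("fold centre lies outside the grid", call. = FALSE)
  }
  co <- coord_arrays(geom)
  dx <- co$x - center[1]; dy <- co$y - center[2]; dz <- co$z - center[3]
  r2 <- dx^2 + dy^2 + dz^2
  w <- (1 - r2 / radius^2)^2
  w[r2 >= radius^2] <- 0
  u <- field$vectors
  u[, , , 1] <- u[, , , 1] - strength * w * dx
  u[, , , 2] <- u[, , , 2] - strength * w * dy
  u[, , , 3] <- u[, , , 3] - strength * w * dz
  out <- displacement_field(geom, u)
  attr(out, "fold_center_jacobian") <- (1 - strength)^3
  out
}

#' Evaluate a field's closed-form Jacobian on its grid
#'
#' Convenience accessor for fields built by the synthetic constructors, which
#' carry their analytic Jacobian as a `jacobian_fn` attribute.
#'
#' @param field A synthetic [displacement_field()].
#' @return A [scalar_volume()] of the closed-form Jacobian at voxel centres.
#' @export
jacobian_truth <- function(field) {
  fn <- attr(field, "jacobian_fn")
  if (is.null(fn)) {
    stop("field carries no closed-form Jacobian (`jacobian_fn` attribute)",
         call. = FALSE)
  }
  co <- coord_arrays(field$geometry)
  vals <- fn(co$x, co$y, co$z)
  scalar_volume(field$geometry, array(vals, dim = field$geometry$dims))
}

#' Synthetic multi-patient cohort with analytic ground truth
#'
#' Emulates a cohort of exhale-to-inhale lung registrations, each solved by
#' two algorithms. Per case, `field_a` is a randomized mix of a diagonal
#' affine expansion (overall inflation, strongest along z) and a z-axis
#' sinusoid (diaphragm-like nonuniform stretch); its pointwise Jacobian is
#' available in closed form. `field_b` adds a smooth band-limited
#' perturbation standing in for inter-algorithm disagreement: a slowly
#' rotating unit direction field scaled by a near-uniform magnitude between
#' 0.9 and 1.0 times `discrepancy`, so the injected discrepancy level is
#' recoverable from high-tail sub-volume statistics. `discrepancy = 0` makes
#' `field_b` identical to `field_a`. Phantom masks ("left_lung",
#' "right_lung", "gtv") are spheres.
#'
#' Generation is a pure function of `(n_patients, seed, discrepancy)`:
#' per-patient streams are derived from the master seed by a fixed offset.
#'
#' @param n_patients Number of cases (`>= 2`).
#' @param seed Master integer seed.
#' @param discrepancy Peak inter-algorithm displacement difference, mm.
#' @param geom A [grid_geometry()]; the default desk-scale phantom grid.
#' @return A list of `synthetic_case` objects, each with elements
#'   `patient_id`, `field_a`, `field_b`, `masks` (named list of
#'   [structure_mask()]), `seed`, and `truth`: `jacobian_a` (closed-form
#'   Jacobian of `field_a` as a [scalar_volume()]), `volume_ratio` (named,
#'   volume-weighted mean of the closed-form Jacobian over each mask), and
#'   `sd_mm` (closed-form magnitude of `field_b - field_a`, mm).
#' @export
make_synthetic_cohort <- function(n_patients, seed, discrepancy = 0,
                                  geom = default_grid()) {
  if (n_patients < 2) stop("`n_patients` must be >= 2", call. = FALSE)
  if (!is.finite(discrepancy) || discrepancy < 0) {
    stop("`discrepancy` must be a non-negative length in mm", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (seed + n_patients * 101L >= .Machine$integer.max) {
    stop("seed too large to derive per-patient streams", call. = FALSE)
  }
  masks <- phantom_masks(geom)
  lapply(seq_len(n_patients), function(i) {
    make_synthetic_case(seed + i * 101L, discrepancy, geom, masks,
                        patient_id = sprintf("case%02d", i))
  })
}

phantom_masks <- function(geom) {
  extent <- geom$origin + (geom$dims - 1) * geom$spacing
  mid <- (geom$origin + extent) / 2
  span <- extent - geom$origin
  r_lung <- 0.2 * min(span)
  list(
    left_lung = make_sphere_mask(mid + c(-0.25 * span[1], 0, 0), r_lung, geom,
                                 label = "left_lung"),
    right_lung = make_sphere_mask(mid + c(0.25 * span[1], 0, 0), r_lung, geom,
                                  label = "right_lung"),
    gtv = make_sphere_mask(mid + c(0.1, 0.12, 0.15) * span,
                           max(0.08 * min(span), 1.2 * max(geom$spacing)),
                           geom, label = "gtv")
  )
}

make_synthetic_case <- function(case_seed, discrepancy, geom, masks, patient_id) {
  draws <- with_local_seed(case_seed, {
    list(
      # inflation strongest along z, mild in-plane
      a_diag = c(stats::runif(2, 0.00, 0.05), stats::runif(1, 0.05, 0.12)),
      t = stats::runif(3, -3, 3),
      amp = stats::runif(1, 3, 8),
      k = stats::runif(1, 0.02, 0.04),
      phase = stats::runif(1, 0, 2 * pi),
      km = stats::runif(3, 0.05, 0.10),
      phim = stats::runif(1, 0, 2 * pi),
      kd = stats::runif(3, 0.03, 0.08),
      phid = stats::runif(3, 0, 2 * pi)
    )
  })
  A <- diag(draws$a_diag)
  aff <- make_affine_field(A, draws$t, geom)
  sinf <- make_axial_sinusoid_field(draws$amp, draws$k, "z", geom,
                                    phase = draws$phase)
  field_a <- displacement_field(geom, aff$vectors + sinf$vectors)

  # closed-form Jacobian of the mix: gradients add, A is diagonal and the
  # sinusoid only contributes to du_z/dz, so the determinant factorizes
  co <- coord_arrays(geom)
  jac_a <- (1 + draws$a_diag[1]) * (1 + draws$a_diag[2]) *
    (1 + draws$a_diag[3] + draws$amp * draws$k * cos(draws$k * co$z + draws$phase))
  truth_jac <- scalar_volume(geom, jac_a)

  volume_ratio <- vapply(masks, function(m) mean(jac_a[m$occupancy]), numeric(1))

  if (discrepancy > 0) {
    m_mag <- discrepancy *
      (0.95 + 0.05 * sin(draws$km[1] * co$x + draws$km[2] * co$y +
                           draws$km[3] * co$z + draws$phim))
    wx <- 0.25 * sin(draws$kd[1] * co$z + draws$phid[1]) + 1
    wy <- 0.25 * cos(draws$kd[2] * co$x + draws$phid[2]) + 0.5
    wz <- 0.25 * sin(draws$kd[3] * co$y + draws$phid[3]) + 0.25
    nrm <- sqrt(wx^2 + wy^2 + wz^2)
    u_b <- field_a$vectors
    u_b[, , , 1] <- u_b[, , , 1] + m_mag * wx / nrm
    u_b[, , , 2] <- u_b[, , , 2] + m_mag * wy / nrm
    u_b[, , , 3] <- u_b[, , , 3] + m_mag * wz / nrm
    field_b <- displacement_field(geom, u_b)
    sd_mm <- scalar_volume(geom, m_mag)
  } else {
    field_b <- field_a
    sd_mm <- scalar_volume(geom, array(0, dim = geom$dims))
  }

  structure(
    list(
      patient_id = patient_id,
      field_a = field_a,
      field_b = field_b,
      masks = masks,
      seed = case_seed,
      truth = list(jacobian_a = truth_jac, volume_ratio = volume_ratio,
                   sd_mm = sd_mm)
    ),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s: %d masks, true volume ratios %s\n",
              x$patient_id, length(x$masks),
              paste(sprintf("%s=%.3f", names(x$truth$volume_ratio),
                            x$truth$volume_ratio), collapse = ", ")))
  invisible(x)
}

# Run code under a fixed RNG state, restoring the caller's state after.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
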