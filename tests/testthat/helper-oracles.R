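# Independent oracles and small fixtures shared across test files.

# Naive weighted tail boundary: full sort + cumulative scan, written from the
# definition and kept independent of the package implementation.
oracle_tail_boundary <- function(value, weight, X, side) {
  ord <- order(value, decreasing = (side == "high"))
  v <- value[ord]; w <- weight[ord]
  target <- X / 100 * sum(weight)
  cum <- cumsum(w)
  v[which(cum >= target)[1]]
}

# Point-in-polygon by the angle-summation (winding parity) method — a
# different algorithm from the package's crossing-number test.
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(i) {
    ang <- 0
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      a1 <- atan2(vy[j] - py[i], vx[j] - px[i])
      a2 <- atan2(vy[k] - py[i], vx[k] - px[i])
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      ang <- ang + d
    }
    abs(ang) > pi  # winding number != 0
  }, logical(1))
}

# Hand-written paired t-test (two-tailed) from the textbook formula.
oracle_paired_t_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  2 * pt(-abs(t_stat), df = n - 1)
}

small_grid <- function(dims = c(10, 9, 8), spacing = c(1.5, 1.2, 2.0),
                       origin = c(-4, 3, 10)) {
  grid_geometry(dims, spacing, origin)
}

random_field <- function(geom, scale = 2, seed = 1) {
  set.seed(seed)
  displacement_field(geom, array(rnorm(prod(geom$dims) * 3, sd = scale),
                                 dim = c(geom$dims, 3)))
}

# Smooth band-limited random field (finite analytic derivatives everywhere).
smooth_field <- function(geom, amp = 3, seed = 1) {
  set.seed(seed)
  co <- dvfqa:::coord_arrays(geom)
  u <- array(0, dim = c(geom$dims, 3))
  for (c_i in 1:3) {
    k <- runif(3, 0.01, 0.05); ph <- runif(3, 0, 2 * pi)
    u[, , , c_i] <- amp * (sin(k[1] * co$x + ph[1]) +
                             sin(k[2] * co$y + ph[2]) +
                             sin(k[3] * co$z + ph[3])) / 3
  }
  displacement_field(geom, u)
}

interior <- function(vals) {
  d <- dim(vals)
  vals[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
}

boundary_shell_values <- function(vals) {
  d <- dim(vals)
  c(vals[c(1, d[1]), , ], vals[, c(1, d[2]), ], vals[, , c(1, d[3])])
}
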