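#' Plot a volume histogram
#'
#' Differential volume-fraction histogram of a JVH or SDVH, the standard
#' visual for judging the spread and tails of a Jacobian or discrepancy
#' distribution over a structure.
#'
#' @param object A `volume_histogram` (see [build_histogram()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.volume_histogram <- function(object, ...) {
  units <- attr(object, "units")
  xlab <- if (identical(units, "cm")) "spatial discrepancy (cm)" else "Jacobian"
  mid <- (object$bin_low + object$bin_high) / 2
  df <- tibble::tibble(mid = mid, volume_fraction = object$volume_fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$volume_fraction)) +
    ggplot2::geom_col(width = diff(range(object$bin_low)) /
                        max(1, nrow(object) - 1), fill = "steelblue") +
    ggplot2::labs(x = xlab, y = "volume fraction",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tail-boundary series
#'
#' Bar chart of high-side tail boundaries against the volume fraction X —
#' each bar is the smallest value found in the worst-X% sub-volume of the
#' structure (the standard spatial-discrepancy summary plot).
#'
#' @param series Tibble from [sd_boundary_series()].
#' @param units Y-axis unit label.
#' @return A ggplot object.
#' @export
plot_sd_boundaries <- function(series, units = "cm") {
  ggplot2::ggplot(series, ggplot2::aes(x = factor(.data$X), y = .data$boundary)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "volume fraction X (%)",
                  y = sprintf("boundary (%s)", units)) +
    ggplot2::theme_minimal()
}

#' Plot one slice of a scalar volume
#'
#' Quick-look axial slice of a Jacobian or discrepancy map, e.g. to inspect
#' a folding defect.
#'
#' @param scalar A [scalar_volume()].
#' @param slice Slice index along z.
#' @return A ggplot object.
#' @export
plot_slice <- function(scalar, slice) {
  stopifnot(inherits(scalar, "scalar_volume"))
  slice <- as.integer(slice)
  if (slice < 1 || slice > scalar$geometry$dims[3]) {
    stop("slice index outside the grid", call. = FALSE)
  }
  sl <- scalar$values[, , slice]
  df <- tibble::tibble(
    x = rep(axis_coords(scalar$geometry, 1), times = ncol(sl)),
    y = rep(axis_coords(scalar$geometry, 2), each = nrow(sl)),
    value = as.vector(sl)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  fill = scalar$units %||% "") +
    ggplot2::theme_minimal()
}
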