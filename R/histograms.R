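#' Differential volume histogram of structure samples
#'
#' Bins sample values and accumulates the volume weight per bin, producing a
#' Jacobian volume histogram (JVH) or spatial-discrepancy volume histogram
#' (SDVH) depending on the map sampled. The default range spans the data with
#' a right-inclusive last bin, so the bin volumes sum exactly to the
#' structure's total volume. With a user-supplied narrower range,
#' out-of-range samples are dropped with a warning. Binning affects the plot
#' only: every summary statistic in this package ([weighted_mean()],
#' [weighted_std()], [tail_boundary()]) is computed bin-free from the samples.
#'
#' @param samples A `structure_samples` tibble (see [sample_structure()]).
#' @param n_bins Number of bins (`>= 1`); default 200, a plotting resolution.
#' @param range Optional `c(lo, hi)` with `lo < hi`; default spans the data.
#' @return A `volume_histogram` tibble with columns `bin_low`, `bin_high`,
#'   `volume_mm3`, `volume_fraction`, plus attributes `total_volume`, `label`
#'   and `units`.
#' @export
build_histogram <- function(samples, n_bins = 200, range = NULL) {
  check_samples(samples)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
  v <- samples$value
  w <- samples$weight
  if (is.null(range)) {
    range <- c(min(v), max(v))
    if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
  }
  if (length(range) != 2L || !all(is.finite(range)) || range[2] <= range[1]) {
    stop("`range` must be an increasing pair", call. = FALSE)
  }
  keep <- v >= range[1] & v <= range[2]
  if (!all(keep)) {
    warning("dropping samples outside the histogram range", call. = FALSE)
    v <- v[keep]; w <- w[keep]
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  vol <- vapply(split(w, factor(idx, levels = seq_len(n_bins))),
                function(ws) sum(ws), numeric(1))
  vol[is.na(vol)] <- 0
  total <- attr(samples, "total_volume")
  out <- tibble::tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    volume_mm3 = unname(vol),
    volume_fraction = unname(vol) / total
  )
  attr(out, "total_volume") <- total
  attr(out, "label") <- attr(samples, "label")
  attr(out, "units") <- attr(samples, "units")
  class(out) <- c("volume_histogram", class(out))
  out
}

#' Volume-weighted mean of structure samples
#'
#' `sum(w_i * v_i) / sum(w_i)`. Applied to Jacobian samples this is the
#' mean of the JVH: under the flow-of-tissue reading of a DVF it estimates
#' the fractional volume change of the whole structure,
#' `V_deformed / V_target = (1/V) * sum(v_i * J_i)`, directly comparable with
#' the volume ratio measured from observer-drawn contours.
#'
#' @param samples A `structure_samples` tibble.
#' @return The weighted mean.
#' @export
weighted_mean <- function(samples) {
  check_samples(samples)
  sum(samples$weight * samples$value) / sum(samples$weight)
}

#' Volume-weighted standard deviation of structure samples
#'
#' Population convention: `sqrt(sum(w_i (v_i - mean)^2) / sum(w_i))`. The
#' spread of a structure's JVH discriminates sharply between registration
#' algorithms even when their means agree.
#'
#' @param samples A `structure_samples` tibble.
#' @return The weighted standard deviation, `>= 0`.
#' @export
weighted_std <- function(samples) {
  check_samples(samples)
  m <- weighted_mean(samples)
  sqrt(sum(samples$weight * (samples$value - m)^2) / sum(samples$weight))
}

#' Fractional-volume tail boundary of a distribution
#'
#' The boundary of the most extreme X% of structure volume, computed from
#' exact weighted order statistics (no binning). High side: samples are taken
#' in descending value order until their cumulative volume first reaches X%
#' of the total; the boundary is the value of the last sample included — the
#' *minimum* value inside the top-X% sub-volume. Low side is the mirror image
#' (the *maximum* value inside the bottom-X% sub-volume). Applied to Jacobian
#' samples this yields the `J_X` physicality screens; applied to spatial
#' discrepancy it yields `(SD)_X`, the smallest disagreement within the
#' worst-X% sub-volume.
#'
#' @param samples A `structure_samples` tibble.
#' @param X Percent of structure volume, `0 < X < 100`.
#' @param side `"high"` or `"low"` tail.
#' @return A one-row tibble with columns `X`, `side`, `boundary`.
#' @examples
#' s <- structure_samples(1:100, rep(1, 100))
#' tail_boundary(s, 2.5, "high")$boundary  # 98
#' tail_boundary(s, 2.5, "low")$boundary   # 3
#' @export
tail_boundary <- function(samples, X, side = c("high", "low")) {
  check_samples(samples)
  side <- match.arg(side)
  if (!is.finite(X) || X <= 0 || X >= 100) {
    stop("`X` must be a percentage strictly between 0 and 100", call. = FALSE)
  }
  ord <- order(samples$value, decreasing = (side == "high"))
  w <- samples$weight[ord]
  target <- X / 100 * sum(samples$weight)
  idx <- which(cumsum(w) >= target)[1]
  if (is.na(idx)) idx <- length(w)
  tibble::tibble(X = X, side = side, boundary = samples$value[ord][idx])
}

#' High-side tail-boundary series
#'
#' [tail_boundary()] on the high side at each volume fraction in `X_list`,
#' the summary used for spatial-discrepancy reporting: each entry is the
#' smallest SD inside the worst-X% sub-volume, non-increasing in X.
#'
#' @param samples A `structure_samples` tibble.
#' @param X_list Percentages; the default covers 2.5--35%.
#' @return A tibble with one row per X (`X`, `side`, `boundary`).
#' @export
sd_boundary_series <- function(samples, X_list = c(2.5, 5, 10, 15, 20, 25, 30, 35)) {
  dplyr::bind_rows(lapply(X_list, function(x) tail_boundary(samples, x, "high")))
}

#' Ratio of mean Jacobian to contour-measured volume change
#'
#' `weighted_mean(samples) / contour_volume_ratio`: 1 means the DVF's mean
#' Jacobian over the structure reproduces the volume change measured from
#' observer contours exactly.
#'
#' @param samples Jacobian `structure_samples`.
#' @param contour_volume_ratio Observer volume ratio, `> 0`.
#' @return The dimensionless ratio.
#' @export
jvh_ratio <- function(samples, contour_volume_ratio) {
  if (!is.finite(contour_volume_ratio) || contour_volume_ratio <= 0) {
    stop("`contour_volume_ratio` must be positive", call. = FALSE)
  }
  weighted_mean(samples) / contour_volume_ratio
}

check_samples <- function(samples) {
  if (!inherits(samples, "structure_samples")) {
    stop("expected `structure_samples` (see sample_structure())", call. = FALSE)
  }
  if (nrow(samples) == 0) stop("empty samples", call. = FALSE)
  invisible(TRUE)
}
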