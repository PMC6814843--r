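#' First-order (gray) intensity features
#'
#' Histogram-free statistics of the ROI intensities, plus entropy and
#' uniformity computed on the fixed-bin-count discretized histogram
#' (`n_bins` levels, base-2 entropy). A constant or single-voxel ROI has
#' all dispersion features 0, entropy 0 and uniformity 1; the result then
#' carries attribute `degenerate = TRUE`.
#'
#' @param volume a [voxel_volume()] (or 3D array).
#' @param mask an [roi_mask()].
#' @param n_bins histogram bins for entropy/uniformity (default 128).
#' @return named numeric vector of 15 features (`FO_*`).
#' @export
first_order_features <- function(volume, mask, n_bins = 128L) {
  if (!inherits(volume, "voxel_volume")) volume <- voxel_volume(volume)
  check_congruent(volume, mask)
  x <- volume$data[mask$data]
  if (length(x) == 0L) stop("first_order_features: empty ROI")
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n  # population moments
  degenerate <- (v == 0)
  if (degenerate) {
    skew <- 0; kurt <- 0
    p <- 1  # single occupied level
  } else {
    skew <- (sum((x - m)^3) / n) / v^1.5
    kurt <- (sum((x - m)^4) / n) / v^2
    lev <- pmin(floor((x - min(x)) / (max(x) - min(x)) * n_bins) + 1L, n_bins)
    p <- tabulate(lev, n_bins) / n
  }
  out <- c(FO_mean = m,
           FO_median = stats::median(x),
           FO_min = min(x),
           FO_max = max(x),
           FO_range = max(x) - min(x),
           FO_variance = v,
           FO_sd = sqrt(v),
           FO_skewness = skew,
           FO_kurtosis = kurt,
           FO_energy = sum(x^2),
           FO_entropy = -sum(xlog2(p)),
           FO_uniformity = sum(p^2),
           FO_rms = sqrt(mean(x^2)),
           FO_mad = mean(abs(x - m)),
           FO_iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)))
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}
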