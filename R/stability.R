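#' Spearman rank correlation with midrank ties
#'
#' Thin, guarded wrapper: requires at least 3 complete pairs; a constant
#' input makes the coefficient undefined and returns `NA` (downstream the
#' stability filter treats `NA` as unstable).
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar in [-1, 1], or `NA`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Test-retest / contour-recontour stability filter
#'
#' For each feature, computes the Spearman correlation between the two
#' members of each pair (`rho_pair`) and between the feature (first
#' member) and the ROI volume (`rho_volume`). A feature is selected when
#' `rho_pair > rho_min` and `|rho_volume| < volume_rho_max` — the second
#' criterion removes volume surrogates, which would be reproducible yet
#' carry no texture information beyond size; the absolute value is used
#' because anti-correlation with volume is equally a volume surrogate.
#' Undefined correlations fail the filter conservatively.
#'
#' @param features_a,features_b data.frames/matrices over the same
#'   subjects (rows) and same features (columns), same order.
#' @param volumes_a ROI volumes of the first member of each pair.
#' @param rho_min pair-correlation threshold (default 0.7).
#' @param volume_rho_max volume-correlation bound (default 0.8).
#' @param pairing_kind `"retest"` or `"recontour"` (metadata only).
#' @return data.frame of class `stability_report` with columns `feature`,
#'   `rho_pair`, `rho_volume`, `selected`, `reason`.
#' @export
run_stability <- function(features_a, features_b, volumes_a,
                          rho_min = 0.7, volume_rho_max = 0.8,
                          pairing_kind = c("retest", "recontour")) {
  pairing_kind <- match.arg(pairing_kind)
  features_a <- as.data.frame(features_a)
  features_b <- as.data.frame(features_b)
  if (!identical(colnames(features_a), colnames(features_b)))
    stop("run_stability: the two feature tables must share one manifest")
  if (nrow(features_a) != nrow(features_b) ||
      nrow(features_a) != length(volumes_a))
    stop("run_stability: subject counts differ between a, b and volumes")
  if (nrow(features_a) < 3L)
    stop("run_stability: need at least 3 subjects")
  res <- lapply(colnames(features_a), function(f) {
    rp <- spearman_cor(features_a[[f]], features_b[[f]])
    rv <- spearman_cor(features_a[[f]], volumes_a)
    sel <- isTRUE(rp > rho_min) && isTRUE(abs(rv) < volume_rho_max)
    reason <- if (is.na(rp)) "rho_pair undefined"
      else if (rp <= rho_min) "not reproducible"
      else if (is.na(rv)) "rho_volume undefined"
      else if (abs(rv) >= volume_rho_max) "volume surrogate"
      else "selected"
    data.frame(feature = f, rho_pair = rp, rho_volume = rv,
               selected = sel, reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "pairing_kind") <- pairing_kind
  attr(out, "rho_min") <- rho_min
  attr(out, "volume_rho_max") <- volume_rho_max
  attr(out, "volume_source") <- "first member of each pair"
  class(out) <- c("stability_report", "data.frame")
  out
}

#' Combine retest and recontour selections
#'
#' A feature must survive both studies, so the combination is the
#' intersection of the two selected sets.
#'
#' @param retest,recontour `stability_report`s over the same manifest.
#' @return character vector of selected feature names.
#' @export
combine_selections <- function(retest, recontour) {
  if (!setequal(retest$feature, recontour$feature))
    stop("combine_selections: reports cover different manifests")
  out <- intersect(retest$feature[retest$selected],
                   recontour$feature[recontour$selected])
  if (length(out) == 0L)
    warning("combine_selections: no feature selected by both studies")
  out
}

#' Plot the distribution of pair correlations
#'
#' One histogram panel per stability report, with the selection threshold
#' marked.
#'
#' @param reports named list of `stability_report`s.
#' @param path output PNG file.
#' @return invisibly, `path`.
#' @export
stability_distribution_plot <- function(reports, path) {
  if (inherits(reports, "stability_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  grDevices::png(path, width = 480 * length(reports), height = 480)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(reports)))
  for (k in seq_along(reports)) {
    r <- reports[[k]]
    ttl <- names(reports)[k]
    if (is.null(ttl) || ttl == "")
      ttl <- attr(r, "pairing_kind")
    graphics::hist(r$rho_pair, breaks = seq(-1, 1, by = 0.05),
                   main = ttl, xlab = "Spearman rho (pair)",
                   col = "grey80")
    graphics::abline(v = attr(r, "rho_min"), col = "red", lty = 2)
  }
  invisible(path)
}
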