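#' Distance-1 offset sets for texture matrices
#'
#' `offsets_3d()` returns the 13 unique 3D voxel offsets at Chebyshev
#' distance 1 (one of each +/- pair of the 26-neighborhood), used on the
#' original image channel. `offsets_2d()` returns the 4 unique in-plane
#' directions (0, 45, 90, 135 degrees), used on 2D wavelet sub-bands.
#'
#' @return list of integer length-3 offsets.
#' @export
offsets_3d <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    o <- c(dx, dy, dz)
    if (all(o == 0)) next
    nz <- o[o != 0]
    if (nz[1] > 0) out[[length(out) + 1L]] <- o  # keep one of each +/- pair
  }
  out
}

#' @rdname offsets_3d
#' @export
offsets_2d <- function() {
  list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(1L, -1L, 0L))
}

# ordered level pairs (i, j) for one offset; both voxels in-ROI
glcm_pairs_count <- function(lev, offset, n_bins) {
  d <- dim(lev)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    s <- offset[k]
    if (abs(s) >= d[k]) return(matrix(0, n_bins, n_bins))
    if (s >= 0) { src[[k]] <- seq_len(d[k] - s); dst[[k]] <- seq_len(d[k] - s) + s }
    else { src[[k]] <- seq_len(d[k] + s) - s; dst[[k]] <- seq_len(d[k] + s) }
  }
  a <- lev[src[[1]], src[[2]], src[[3]]]
  b <- lev[dst[[1]], dst[[2]], dst[[3]]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, n_bins, n_bins))
  counts <- tabulate(a[ok] + (b[ok] - 1L) * n_bins, nbins = n_bins * n_bins)
  matrix(counts, n_bins, n_bins)
}

#' Gray-level co-occurrence matrix
#'
#' Counts discretized level pairs at the given distance-1 offsets, within
#' the ROI only (both voxels of a pair must be foreground). Each
#' per-direction matrix is symmetrized, normalized to probabilities, and
#' the directions are aggregated by averaging the normalized matrices.
#'
#' @param d a [discretize()]d ROI.
#' @param offsets list of integer offsets (default [offsets_3d()]).
#' @param symmetric symmetrize each directional matrix (default TRUE).
#' @return An object of class `glcm`: `matrix` (n_bins x n_bins, sums to
#'   1), `direction_count`, `n_bins`.
#' @export
glcm_compute <- function(d, offsets = offsets_3d(), symmetric = TRUE) {
  stopifnot(inherits(d, "discretized_roi"))
  nb <- d$n_bins
  acc <- matrix(0, nb, nb)
  used <- 0L
  for (o in offsets) {
    cnt <- glcm_pairs_count(d$levels, o, nb)
    if (symmetric) cnt <- cnt + t(cnt)
    s <- sum(cnt)
    if (s > 0) { acc <- acc + cnt / s; used <- used + 1L }
  }
  if (used == 0L)
    stop("degenerate ROI for GLCM: no in-ROI voxel pairs at distance 1")
  structure(list(matrix = acc / used, direction_count = used, n_bins = nb),
            class = "glcm")
}

# 0*log2(0) := 0
xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' GLCM texture features
#'
#' The 24 co-occurrence features of the bank (Haralick-style set plus a
#' marginal gray-level nonuniformity `GLN`, the co-occurrence analogue of
#' the run-length GLN). All use the convention 0*log(0) = 0.
#'
#' @param g a [glcm_compute()] result.
#' @return named numeric vector of 24 features (names without channel
#'   prefix, e.g. `GLCM_contrast`).
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  P <- g$matrix
  nb <- g$n_bins
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(nb) * px); mu_y <- sum(seq_len(nb) * py)
  sd_x <- sqrt(sum((seq_len(nb) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(nb) - mu_y)^2 * py))
  # diagonal (|i-j| = k) and cross-diagonal (i+j = k) marginals
  k_diff <- 0:(nb - 1)
  p_diff <- sapply(k_diff, function(k) sum(P[abs(i - j) == k]))
  k_sum <- 2:(2 * nb)
  p_sum <- sapply(k_sum, function(k) sum(P[(i + j) == k]))
  HX <- -sum(xlog2(px)); HY <- -sum(xlog2(py))
  HXY <- -sum(xlog2(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(P * ifelse(pxy > 0, log2(pxy), 0))
  HXY2 <- -sum(xlog2(pxy))
  da <- sum(k_diff * p_diff)
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  corr <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y) else 1
  offd <- i != j
  c(GLCM_autocorrelation   = sum(i * j * P),
    GLCM_cluster_prominence = sum((i + j - mu_x - mu_y)^4 * P),
    GLCM_cluster_shade     = sum((i + j - mu_x - mu_y)^3 * P),
    GLCM_cluster_tendency  = sum((i + j - mu_x - mu_y)^2 * P),
    GLCM_contrast          = sum((i - j)^2 * P),
    GLCM_correlation       = corr,
    GLCM_difference_average = da,
    GLCM_difference_entropy = -sum(xlog2(p_diff)),
    GLCM_difference_variance = sum((k_diff - da)^2 * p_diff),
    GLCM_dissimilarity     = sum(abs(i - j) * P),
    GLCM_joint_energy      = sum(P^2),
    GLCM_joint_entropy     = HXY,
    GLCM_imc1              = imc1,
    GLCM_imc2              = imc2,
    GLCM_idm               = sum(P / (1 + (i - j)^2)),
    GLCM_idmn              = sum(P / (1 + ((i - j) / nb)^2)),
    GLCM_id                = sum(P / (1 + abs(i - j))),
    GLCM_idn               = sum(P / (1 + abs(i - j) / nb)),
    GLCM_inverse_variance  = sum(P[offd] / (i[offd] - j[offd])^2),
    GLCM_max_probability   = max(P),
    GLCM_sum_average       = sum(k_sum * p_sum),
    GLCM_sum_entropy       = -sum(xlog2(p_sum)),
    GLCM_sum_squares       = sum((i - mu_x)^2 * P),
    GLCM_GLN               = sum(px^2))
}
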