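# single-level 1D Haar along the rows of a matrix (orthonormal,
# sqrt(2)-normalized); odd lengths are padded by edge replication
haar_step <- function(M) {
  n <- nrow(M)
  if (n %% 2 == 1L) M <- rbind(M, M[n, , drop = FALSE])
  oi <- seq(1L, nrow(M), by = 2L)
  list(lo = (M[oi, , drop = FALSE] + M[oi + 1L, , drop = FALSE]) / sqrt(2),
       hi = (M[oi, , drop = FALSE] - M[oi + 1L, , drop = FALSE]) / sqrt(2))
}

# 2D single-level Haar DWT of one slice: rows first (x), then columns (y)
haar_dwt2 <- function(S) {
  rx <- haar_step(S)
  ll_lh <- haar_step(t(rx$lo))
  hl_hh <- haar_step(t(rx$hi))
  list(LL = t(ll_lh$lo), LH = t(ll_lh$hi),
       HL = t(hl_hh$lo), HH = t(hl_hh$hi))
}

#' Slice-wise 2D Haar wavelet sub-bands
#'
#' Applies a single-level 2D discrete Haar transform to every axial slice
#' of the volume, producing four half-resolution sub-band volumes: LL
#' (approximation), LH / HL (horizontal / vertical detail) and HH
#' (diagonal detail). The transform is orthonormal, so for even in-plane
#' dimensions the summed energy of the four sub-bands equals the input
#' energy (Parseval); odd dimensions are edge-padded. In-plane spacing of
#' the sub-band grids is doubled.
#'
#' @param volume a [voxel_volume()] with at least 2 voxels per in-plane
#'   axis.
#' @return named list of four [voxel_volume()]s (`LL`, `LH`, `HL`, `HH`).
#' @export
wavelet_channels <- function(volume) {
  if (!inherits(volume, "voxel_volume")) volume <- voxel_volume(volume)
  d <- dim(volume$data)
  if (d[1] < 2L || d[2] < 2L)
    stop("wavelet_channels: slices must be at least 2x2 for the Haar filter")
  nxo <- ceiling(d[1] / 2); nyo <- ceiling(d[2] / 2)
  out <- list(LL = NULL, LH = NULL, HL = NULL, HH = NULL)
  arrs <- lapply(out, function(.) array(0, c(nxo, nyo, d[3])))
  for (z in seq_len(d[3])) {
    w <- haar_dwt2(volume$data[, , z])
    for (b in names(arrs)) arrs[[b]][, , z] <- w[[b]]
  }
  sp <- volume$spacing_mm * c(2, 2, 1)
  lapply(arrs, voxel_volume, spacing_mm = sp, origin = volume$origin)
}

#' Downsample an ROI mask to a wavelet sub-band grid
#'
#' A sub-band voxel is foreground when any voxel of its 2x2 in-plane
#' source block is foreground, so the ROI never vanishes at half
#' resolution.
#'
#' @param mask an [roi_mask()] on the original grid.
#' @return an [roi_mask()] on the half-resolution in-plane grid.
#' @export
downsample_mask <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$data
  d <- dim(m)
  if (d[1] %% 2 == 1L) m <- m[c(seq_len(d[1]), d[1]), , , drop = FALSE]
  if (d[2] %% 2 == 1L) m <- m[, c(seq_len(d[2]), d[2]), , drop = FALSE]
  d <- dim(m)
  xi <- seq(1L, d[1], 2L); yi <- seq(1L, d[2], 2L)
  blk <- m[xi, , , drop = FALSE] | m[xi + 1L, , , drop = FALSE]
  blk <- blk[, yi, , drop = FALSE] | blk[, yi + 1L, , drop = FALSE]
  roi_mask(blk, mask$spacing_mm * c(2, 2, 1))
}
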