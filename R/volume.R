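#' Voxel volume container
#'
#' A 3D scalar image (Hounsfield units for CT) with voxel spacing and a
#' physical origin. All geometric quantities downstream are computed in mm
#' via `spacing_mm`; voxel indices are 0-based in physical coordinates.
#'
#' @param data numeric 3D array.
#' @param spacing_mm numeric length-3, strictly positive voxel size in mm.
#' @param origin numeric length-3 physical offset (mm).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing_mm = c(1.12, 1.12, 1.12),
                         origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("voxel_volume: `data` must be a 3D array, got ",
         length(dim(data)), " dimensions")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("voxel_volume: `spacing_mm` must be 3 strictly positive values")
  if (any(!is.finite(data)))
    stop("voxel_volume: `data` contains non-finite values")
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' Binary region-of-interest mask
#'
#' A binary 3D mask congruent with its [voxel_volume()]. Any nonzero value
#' is foreground.
#'
#' @param data logical/numeric 3D array; nonzero marks the ROI.
#' @param spacing_mm voxel size in mm (must match the paired volume).
#' @return An object of class `roi_mask` with logical `data`.
#' @export
roi_mask <- function(data, spacing_mm = c(1.12, 1.12, 1.12)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("roi_mask: `data` must be a 3D array")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  structure(list(data = array(data != 0, dim(data)),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "roi_mask")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

check_congruent <- function(volume, mask) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume grid [", paste(dim(volume$data), collapse = "x"),
         "] and mask grid [", paste(dim(mask$data), collapse = "x"),
         "] are not congruent")
  if (max(abs(volume$spacing_mm - mask$spacing_mm)) > 1e-6)
    stop("volume spacing (", paste(volume$spacing_mm, collapse = ", "),
         ") and mask spacing (", paste(mask$spacing_mm, collapse = ", "),
         ") differ")
  invisible(TRUE)
}

#' ROI voxel count and physical volume
#' @param mask an [roi_mask()].
#' @return volume in mm^3.
#' @export
roi_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$data) * prod(mask$spacing_mm)
}

#' Write a volume/mask pair as NIfTI
#'
#' @param volume a [voxel_volume()]; @param mask an [roi_mask()].
#' @param volume_path,mask_path output paths (.nii or .nii.gz).
#' @return invisibly, the two paths.
#' @export
write_volume_mask <- function(volume, mask, volume_path, mask_path) {
  check_congruent(volume, mask)
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, volume_path)
  msk <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(msk) <- mask$spacing_mm
  RNifti::writeNifti(msk, mask_path)
  invisible(c(volume = volume_path, mask = mask_path))
}

#' Read a volume/mask pair from NIfTI
#'
#' Grids must be congruent; spacing is preserved, never resampled.
#'
#' @param volume_path,mask_path NIfTI files.
#' @return list(volume = [voxel_volume()], mask = [roi_mask()]).
#' @export
read_volume_mask <- function(volume_path, mask_path) {
  if (!file.exists(volume_path)) stop("no such file: ", volume_path)
  if (!file.exists(mask_path)) stop("no such file: ", mask_path)
  vimg <- RNifti::readNifti(volume_path)
  mimg <- RNifti::readNifti(mask_path)
  vsp <- RNifti::pixdim(vimg)[1:3]
  msp <- RNifti::pixdim(mimg)[1:3]
  vol <- voxel_volume(array(as.numeric(vimg), dim(vimg)[1:3]), vsp)
  msk <- roi_mask(array(as.numeric(mimg), dim(mimg)[1:3]), msp)
  check_congruent(vol, msk)
  list(volume = vol, mask = msk)
}

#' Fixed-bin-count gray-level discretization of an ROI
#'
#' Maps the ROI intensity range [min, max] into `n_bins` equal-width bins;
#' the maximum maps to bin `n_bins`. This fixed bin *number* over the ROI
#' range is the dialect used by all second-order texture features here
#' (default 128 levels), and it makes every second-order feature invariant
#' to affine rescaling x -> a*x + b (a > 0) of the ROI intensities.
#'
#' @param volume a [voxel_volume()] (or bare 3D array).
#' @param mask an [roi_mask()] congruent with `volume`.
#' @param n_bins number of gray levels (>= 2), default 128.
#' @return An object of class `discretized_roi`: `levels` is an integer
#'   array shaped like the volume with NA outside the ROI and values in
#'   1..n_bins inside; plus `n_bins`, `bin_edges`, `spacing_mm`.
#' @export
discretize <- function(volume, mask, n_bins = 128L) {
  if (!inherits(volume, "voxel_volume")) volume <- voxel_volume(volume)
  check_congruent(volume, mask)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("discretize: n_bins must be >= 2")
  inroi <- mask$data
  if (!any(inroi)) stop("discretize: empty ROI (no foreground voxels)")
  x <- volume$data[inroi]
  lo <- min(x); hi <- max(x)
  lev <- array(NA_integer_, dim(volume$data))
  if (hi == lo) {
    warning("discretize: constant ROI intensity; all voxels assigned level 1")
    lev[inroi] <- 1L
    edges <- c(lo, hi)
  } else {
    l <- floor((x - lo) / (hi - lo) * n_bins) + 1L
    l[l > n_bins] <- n_bins  # max maps into the top bin
    lev[inroi] <- as.integer(l)
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  structure(list(levels = lev, n_bins = n_bins, bin_edges = edges,
                 spacing_mm = volume$spacing_mm),
            class = "discretized_roi")
}
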