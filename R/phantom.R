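#' Phantom specification
#'
#' Describes a synthetic ellipsoidal tumor on a CT-like grid. Intra-tumor
#' texture is a stationary Gaussian random field obtained by Gaussian
#' spectral filtering of white noise; `texture_corr_length_mm` is the
#' kernel standard deviation in mm and controls heterogeneity (long
#' correlation length = smooth/homogeneous tumor), `texture_sd` its
#' marginal standard deviation in HU. Independent white scanner noise of
#' sd `noise_sd` HU is added on top.
#'
#' @param grid_shape voxels per axis (length 3 or scalar).
#' @param spacing_mm voxel size in mm (planning CTs here are ~1.12 mm
#'   in-plane); scalar or length 3.
#' @param tumor_radius_mm ellipsoid semi-axes in mm (scalar or length 3).
#' @param texture_corr_length_mm correlation length of the texture field (> 0).
#' @param texture_sd texture field standard deviation (HU).
#' @param mean_hu tumor mean intensity (HU).
#' @param noise_sd white scanner noise sd (HU).
#' @param background_hu intensity outside the tumor.
#' @param seed integer seed; all phantom randomness flows from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         spacing_mm = c(1.12, 1.12, 1.12),
                         tumor_radius_mm = c(16, 14, 12),
                         texture_corr_length_mm = 4,
                         texture_sd = 30,
                         mean_hu = 40,
                         noise_sd = 10,
                         background_hu = -70,
                         seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(tumor_radius_mm) == 1L) tumor_radius_mm <- rep(tumor_radius_mm, 3L)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape <= 0)) stop("phantom_spec: grid_shape must be positive")
  if (any(spacing_mm <= 0)) stop("phantom_spec: spacing_mm must be positive")
  if (texture_corr_length_mm <= 0)
    stop("phantom_spec: texture_corr_length_mm must be > 0")
  half_extent <- grid_shape * spacing_mm / 2
  if (any(tumor_radius_mm >= half_extent))
    stop("phantom_spec: tumor (semi-axes ",
         paste(tumor_radius_mm, collapse = ", "),
         " mm) does not fit inside the grid (half-extent ",
         paste(signif(half_extent, 4), collapse = ", "), " mm)")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 texture_corr_length_mm = texture_corr_length_mm,
                 texture_sd = texture_sd, mean_hu = mean_hu,
                 noise_sd = noise_sd, background_hu = background_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Stationary Gaussian random field: white noise circularly convolved with a
# Gaussian kernel (FFT), then standardized to unit marginal sd. Returns an
# array of dim `shape`. Assumes the RNG state is already set by the caller.
gaussian_field <- function(shape, spacing_mm, corr_mm) {
  w <- array(stats::rnorm(prod(shape)), shape)
  # wraparound distance along each axis, in mm
  ax <- lapply(seq_len(3L), function(a) {
    i <- seq_len(shape[a]) - 1L
    (pmin(i, shape[a] - i) * spacing_mm[a])^2
  })
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  k <- exp(-d2 / (2 * corr_mm^2))
  f <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) /
    prod(shape)
  f <- f - mean(f)  # zero spatial mean, then unit marginal sd
  s <- stats::sd(as.vector(f))
  if (s == 0) f else f / s
}

ellipsoid_mask <- function(shape, spacing_mm, radius_mm) {
  ctr <- (shape - 1) / 2 * spacing_mm
  ax <- lapply(seq_len(3L), function(a) {
    x <- (seq_len(shape[a]) - 1L) * spacing_mm[a]
    ((x - ctr[a]) / radius_mm[a])^2
  })
  d <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  d <= 1
}

# Deterministic phantom pieces given a spec: the ellipsoid indicator and the
# texture field (seeded); scanner noise is drawn separately so retest pairs
# can share the texture but not the noise.
phantom_base <- function(spec) {
  msk <- ellipsoid_mask(spec$grid_shape, spec$spacing_mm, spec$tumor_radius_mm)
  set.seed(spec$seed)
  tex <- if (spec$texture_sd > 0)
    spec$texture_sd * gaussian_field(spec$grid_shape, spec$spacing_mm,
                                     spec$texture_corr_length_mm)
  else array(0, spec$grid_shape)
  base <- array(spec$background_hu, spec$grid_shape)
  base[msk] <- spec$mean_hu
  list(base = base + tex, mask = msk)
}

#' Generate a textured tumor phantom
#'
#' Interior intensity = `mean_hu` + correlated Gaussian texture field +
#' white scanner noise; the mask marks the ellipsoid. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list(volume = [voxel_volume()], mask = [roi_mask()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  pb <- phantom_base(spec)
  set.seed(spec$seed + 1L)
  noise <- if (spec$noise_sd > 0)
    array(stats::rnorm(prod(spec$grid_shape), 0, spec$noise_sd),
          spec$grid_shape)
  else 0
  list(volume = voxel_volume(pb$base + noise, spec$spacing_mm),
       mask = roi_mask(pb$mask, spec$spacing_mm))
}

# integer-voxel rigid shift with constant fill
shift_array <- function(a, shift, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) { src[[k]] <- seq_len(d[k] - s); dst[[k]] <- seq_len(d[k] - s) + s }
    else { src[[k]] <- seq_len(d[k] + s) - s; dst[[k]] <- seq_len(d[k] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate a test-retest phantom pair
#'
#' Two scans of the same underlying tumor: the texture field is shared,
#' while each scan receives an independent white-noise realization and,
#' optionally, a small rigid shift (rounded to whole voxels); the mask is
#' re-derived under the same shift.
#'
#' @param spec a [phantom_spec()].
#' @param perturb `NULL` for no perturbation (the two scans are then
#'   identical), or a list with elements `noise_sd` (rescan noise, default
#'   `spec$noise_sd`) and `shift_mm` (length-3 rigid offset of scan 2,
#'   default 0).
#' @return list(scan1 = list(volume, mask), scan2 = list(volume, mask)).
#' @export
make_retest_pair <- function(spec, perturb = list()) {
  stopifnot(inherits(spec, "phantom_spec"))
  scan1 <- make_phantom(spec)
  if (is.null(perturb)) return(list(scan1 = scan1, scan2 = scan1))
  noise_sd <- if (is.null(perturb$noise_sd)) spec$noise_sd else perturb$noise_sd
  shift_mm <- if (is.null(perturb$shift_mm)) c(0, 0, 0) else perturb$shift_mm
  shift_vox <- as.integer(round(shift_mm / spec$spacing_mm))
  pb <- phantom_base(spec)
  base2 <- shift_array(pb$base, shift_vox, spec$background_hu)
  mask2 <- shift_array(pb$mask, shift_vox, FALSE)
  set.seed(spec$seed + 2L)
  noise2 <- if (noise_sd > 0)
    array(stats::rnorm(prod(spec$grid_shape), 0, noise_sd), spec$grid_shape)
  else 0
  list(scan1 = scan1,
       scan2 = list(volume = voxel_volume(base2 + noise2, spec$spacing_mm),
                    mask = roi_mask(mask2, spec$spacing_mm)))
}

# zero-padded Gaussian smoothing (no wraparound across the grid edge)
gaussian_smooth_padded <- function(a, spacing_mm, sigma_mm) {
  d <- dim(a)
  pad <- pmin(ceiling(4 * sigma_mm / spacing_mm), d)
  dp <- d + 2L * pad
  ap <- array(0, dp)
  ix <- lapply(1:3, function(k) seq_len(d[k]) + pad[k])
  ap[ix[[1]], ix[[2]], ix[[3]]] <- a
  sm <- gaussian_smooth(ap, spacing_mm, sigma_mm)
  sm[ix[[1]], ix[[2]], ix[[3]]]
}

# 3D Gaussian smoothing in mm units (FFT, circular)
gaussian_smooth <- function(a, spacing_mm, sigma_mm) {
  d <- dim(a)
  ax <- lapply(seq_len(3L), function(k) {
    i <- seq_len(d[k]) - 1L
    (pmin(i, d[k] - i) * spacing_mm[k])^2
  })
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  k <- exp(-d2 / (2 * sigma_mm^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(a) * stats::fft(k), inverse = TRUE)) / prod(d)
}

#' Generate a re-contour of an ROI mask
#'
#' Emulates inter-observer delineation variability: the mask boundary is
#' displaced along its normal by a smooth random field of amplitude
#' `boundary_sd_mm`. The signed distance to the boundary is approximated
#' from a Gaussian-smoothed copy of the mask indicator, so the
#' perturbation applies to arbitrary mask shapes. The Dice overlap with
#' the original mask is attached as attribute `"dice"`.
#'
#' @param volume the [voxel_volume()] the mask belongs to (spacing source).
#' @param mask the original [roi_mask()]; must be nonempty.
#' @param boundary_sd_mm sd of the boundary displacement field (mm); 0
#'   returns the original mask unchanged.
#' @param seed integer seed.
#' @param corr_mm correlation length of the displacement field (default
#'   3 mm: observers disagree over boundary segments, not single voxels,
#'   but also not coherently over the whole tumor).
#' @return A new [roi_mask()] with attribute `dice`.
#' @export
make_recontour_pair <- function(volume, mask, boundary_sd_mm, seed,
                                corr_mm = 3) {
  check_congruent(volume, mask)
  if (!any(mask$data)) stop("make_recontour_pair: empty mask")
  if (boundary_sd_mm == 0) {
    out <- mask
    attr(out, "dice") <- 1
    return(out)
  }
  sp <- mask$spacing_mm
  sig <- max(sp)  # smoothing scale of the indicator, mm
  g <- gaussian_smooth_padded(array(as.numeric(mask$data), dim(mask$data)),
                              sp, sig)
  g <- pmin(pmax(g, 1e-7), 1 - 1e-7)
  d_signed <- -sig * stats::qnorm(g)  # ~ mm outside boundary (negative inside)
  set.seed(seed)
  u <- boundary_sd_mm * gaussian_field(dim(mask$data), sp, corr_mm)
  # displacements beyond the signed-distance validity band are
  # meaningless at this smoothing resolution; saturate them (the band is
  # narrower than the distance clamp, so far-field voxels can never be
  # swept into the mask)
  u <- pmin(pmax(u, -3 * sig), 3 * sig)
  new <- d_signed <= u
  if (!any(new) || !any(new & mask$data))
    stop("make_recontour_pair: perturbation emptied or displaced the mask ",
         "away from the original contour (boundary_sd_mm too large for ",
         "this ROI)")
  out <- roi_mask(new, sp)
  inter <- sum(new & mask$data)
  attr(out, "dice") <- 2 * inter / (sum(new) + sum(mask$data))
  out
}
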