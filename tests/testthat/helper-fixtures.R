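# build a discretized_roi directly from a matrix/array of levels
# (NA = outside ROI); used to hand-feed texture-matrix oracles
disc_from_levels <- function(levels, n_bins = max(levels, na.rm = TRUE)) {
  a <- as.array(levels)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  structure(list(levels = array(as.integer(a), dim(a)),
                 n_bins = as.integer(n_bins),
                 bin_edges = seq(0, n_bins),
                 spacing_mm = c(1, 1, 1)),
            class = "discretized_roi")
}

# small fast phantom spec for tests
tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(grid_shape = 24L, spacing_mm = 1, tumor_radius_mm = c(9, 8, 7),
         texture_corr_length_mm = 3, texture_sd = 25, noise_sd = 8,
         seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# empirical lag-1 autocorrelation of ROI voxels along the first axis
roi_lag1_autocor <- function(volume, mask) {
  v <- volume$data
  m <- mask$data
  d <- dim(v)
  a <- v[-d[1], , ]; b <- v[-1, , ]
  ok <- m[-d[1], , ] & m[-1, , ]
  stats::cor(a[ok], b[ok])
}
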