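#' Extract the radiomics feature bank for one volume/mask pair
#'
#' Evaluates every manifest entry on its image channel. Second-order
#' (GLCM/GLRLM) features use 128-level fixed-bin-count discretization of
#' the channel ROI; the original channel uses the 13 unique 3D distance-1
#' directions, wavelet sub-bands the 4 in-plane directions. GLCM
#' directions are aggregated by averaging normalized matrices, GLRLM by
#' averaging per-direction features. Shape features are computed on the
#' original mask only. No resampling or filtering is applied before
#' extraction.
#'
#' @param volume a [voxel_volume()].
#' @param mask a congruent, nonempty [roi_mask()].
#' @param manifest a `feature_manifest` (default [default_manifest()]).
#' @param n_bins gray levels for second-order discretization (default 128).
#' @return named numeric vector in manifest order with attributes
#'   `roi_volume_mm3` and (if any entry failed) `failed` — failed entries
#'   are returned as `NA`, never dropped.
#' @export
extract_features <- function(volume, mask, manifest = default_manifest(),
                             n_bins = 128L) {
  if (!inherits(volume, "voxel_volume")) volume <- voxel_volume(volume)
  check_congruent(volume, mask)
  if (!any(mask$data)) stop("extract_features: empty ROI")
  channels <- unique(manifest$channel)
  wav_needed <- any(channels != "original")
  chan_data <- list(original = list(volume = volume, mask = mask))
  if (wav_needed) {
    wav <- wavelet_channels(volume)
    dmask <- downsample_mask(mask)
    for (b in intersect(channels, names(wav)))
      chan_data[[b]] <- list(volume = wav[[b]], mask = dmask)
  }

  # per (channel, family) feature blocks, computed once each
  values <- list()
  for (ch in channels) {
    cd <- chan_data[[ch]]
    fams <- unique(manifest$family[manifest$channel == ch])
    dirs <- if (ch == "original") offsets_3d() else offsets_2d()
    disc <- NULL
    for (fam in fams) {
      key <- paste(ch, fam, sep = ".")
      values[[key]] <- tryCatch({
        if (fam %in% c("GLCM", "GLRLM") && is.null(disc))
          disc <- suppressWarnings(discretize(cd$volume, cd$mask, n_bins))
        switch(fam,
          FO = first_order_features(cd$volume, cd$mask, n_bins),
          SHAPE = shape_features(cd$mask),
          GLCM = glcm_features(glcm_compute(disc, dirs)),
          GLRLM = glrlm_features_mean(disc, dirs),
          stop("unknown feature family: ", fam))
      }, error = function(e) {
        structure(numeric(0), msg = conditionMessage(e))
      })
    }
  }

  out <- rep(NA_real_, nrow(manifest))
  names(out) <- manifest$name
  failed <- character(0)
  for (r in seq_len(nrow(manifest))) {
    key <- paste(manifest$channel[r], manifest$family[r], sep = ".")
    block <- values[[key]]
    fname <- paste0(manifest$family[r], "_", manifest$formula_id[r])
    if (length(block) && fname %in% names(block)) {
      out[r] <- block[[fname]]
    } else {
      failed <- c(failed, manifest$name[r])
    }
  }
  attr(out, "roi_volume_mm3") <- roi_volume_mm3(mask)
  if (length(failed)) attr(out, "failed") <- failed
  out
}

#' Extract features for a list of cases
#'
#' @param cases named list; each element a list with `volume` and `mask`.
#' @param manifest,n_bins passed to [extract_features()].
#' @return data.frame: one row per case, columns = manifest names plus
#'   `roi_volume`.
#' @export
extract_cohort_features <- function(cases, manifest = default_manifest(),
                                    n_bins = 128L) {
  rows <- lapply(cases, function(cs) {
    fv <- extract_features(cs$volume, cs$mask, manifest, n_bins)
    c(fv, roi_volume = attr(fv, "roi_volume_mm3"))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- names(cases)
  out
}
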