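#' Feature manifest
#'
#' The manifest is the configuration that defines the feature bank: an
#' ordered table with columns `name` (unique output name), `channel`
#' (`original` or a wavelet sub-band `LL`/`LH`/`HL`/`HH`), `family`
#' (`FO`, `SHAPE`, `GLCM`, `GLRLM`) and `formula_id` (the feature within
#' its family). The default manifest shipped with the package has 271
#' entries: 63 on the original channel (15 first-order + 8 shape +
#' 24 GLCM + 16 GLRLM) and 52 on each of the four wavelet sub-bands
#' (13 first-order + 23 GLCM + 16 GLRLM). Being a file, the composition
#' can be corrected without touching code.
#'
#' @param path CSV file; default is the manifest installed with the
#'   package.
#' @return data.frame of class `feature_manifest`.
#' @export
read_manifest <- function(path = system.file("extdata",
                                             "feature_manifest.csv",
                                             package = "ctradiomics")) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "channel", "family", "formula_id")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(m$name))
    stop("manifest feature names must be unique")
  class(m) <- c("feature_manifest", "data.frame")
  m
}

#' @rdname read_manifest
#' @export
default_manifest <- function() read_manifest()

# family formula lists (single source for manifest generation)
fo_formulas <- function() c("mean", "median", "min", "max", "range",
                            "variance", "sd", "skewness", "kurtosis",
                            "energy", "entropy", "uniformity", "rms",
                            "mad", "iqr")
shape_formulas <- function() c("volume", "surface_area", "sphericity",
                               "compactness1", "compactness2",
                               "spherical_disproportion",
                               "surface_to_volume", "max_diameter_3d")
glcm_formulas <- function() c("autocorrelation", "cluster_prominence",
                              "cluster_shade", "cluster_tendency",
                              "contrast", "correlation",
                              "difference_average", "difference_entropy",
                              "difference_variance", "dissimilarity",
                              "joint_energy", "joint_entropy", "imc1",
                              "imc2", "idm", "idmn", "id", "idn",
                              "inverse_variance", "max_probability",
                              "sum_average", "sum_entropy", "sum_squares",
                              "GLN")
glrlm_formulas <- function() c("SRE", "LRE", "GLN", "GLNN", "RLN", "RLNN",
                               "RP", "GLV", "RLV", "RE", "LGLRE", "HGLRE",
                               "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE")

#' Build the default manifest table
#'
#' Programmatic constructor for the shipped manifest file (used to
#' regenerate `inst/extdata/feature_manifest.csv`).
#'
#' @return data.frame of class `feature_manifest` (271 rows).
#' @export
build_default_manifest <- function() {
  row_block <- function(channel, family, formulas) {
    prefix <- if (channel == "original") "" else paste0(channel, "_")
    data.frame(name = paste0(prefix, family, "_", formulas),
               channel = channel, family = family, formula_id = formulas,
               stringsAsFactors = FALSE)
  }
  blocks <- list(
    row_block("original", "FO", fo_formulas()),
    row_block("original", "SHAPE", shape_formulas()),
    row_block("original", "GLCM", glcm_formulas()),
    row_block("original", "GLRLM", glrlm_formulas())
  )
  wav_fo <- setdiff(fo_formulas(), c("median", "iqr"))       # 13
  wav_glcm <- setdiff(glcm_formulas(), "correlation")        # 23
  for (b in c("LL", "LH", "HL", "HH")) {
    blocks <- c(blocks, list(
      row_block(b, "FO", wav_fo),
      row_block(b, "GLCM", wav_glcm),
      row_block(b, "GLRLM", glrlm_formulas())
    ))
  }
  m <- do.call(rbind, blocks)
  rownames(m) <- NULL
  class(m) <- c("feature_manifest", "data.frame")
  m
}
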