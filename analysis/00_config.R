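# Shared settings for the analysis scripts. Everything downstream is
# deterministic given MASTER_SEED; tables land in results/analysis/.
library(ctradiomics)

MASTER_SEED <- 1L
OUT <- "results/analysis"
N_PATIENTS <- 80L
N_RETEST <- 15L      # retest sub-study size
N_RECONTOUR <- 15L   # recontour sub-study size
GRID <- 32L
BASE_RADII <- c(12, 10, 9)      # mm, ellipsoid semi-axes before jitter
CORR_RANGE <- c(1.5, 6)         # mm, texture correlation length range
RADIOMIC_EFFECT <- -0.6         # log-hazard per sd of heterogeneity
CENSOR_RATE <- 0.3

dir.create(file.path(OUT, "phantoms"), recursive = TRUE,
           showWarnings = FALSE)

# per-patient generative parameters (sizes and heterogeneity vary across
# the cohort; a constant-size cohort would make the volume criterion of
# the stability filter vacuous)
patient_params <- function() {
  set.seed(MASTER_SEED)
  data.frame(
    patient_id = sprintf("P%04d", seq_len(N_PATIENTS)),
    corr_length = runif(N_PATIENTS, CORR_RANGE[1], CORR_RANGE[2]),
    rx = BASE_RADII[1] * runif(N_PATIENTS, 0.6, 1.2),
    ry = BASE_RADII[2] * runif(N_PATIENTS, 0.6, 1.2),
    rz = BASE_RADII[3] * runif(N_PATIENTS, 0.6, 1.2)
  )
}

patient_spec <- function(p, i) {
  phantom_spec(grid_shape = GRID,
               tumor_radius_mm = c(p$rx[i], p$ry[i], p$rz[i]),
               texture_corr_length_mm = p$corr_length[i],
               seed = MASTER_SEED * 1000L + i)
}
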