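#!/usr/bin/env Rscript
# Extract the 271-feature bank for every phantom written by 01_simulate.R
# (reading the NIfTI pairs back from disk) and write the cohort feature
# table.
source("analysis/00_config.R")

p <- patient_params()
cases <- lapply(seq_len(N_PATIENTS), function(i) {
  read_volume_mask(
    file.path(OUT, "phantoms", paste0(p$patient_id[i], "_vol.nii.gz")),
    file.path(OUT, "phantoms", paste0(p$patient_id[i], "_mask.nii.gz")))
})
names(cases) <- p$patient_id

t0 <- Sys.time()
feats <- extract_cohort_features(cases)
cat(sprintf("Extracted %d features x %d patients in %.0f s\n",
            ncol(feats) - 1, nrow(feats),
            as.numeric(Sys.time() - t0, units = "secs")))

write.csv(cbind(patient_id = rownames(feats), feats),
          file.path(OUT, "features.csv"), row.names = FALSE)
cat("Feature table:", file.path(OUT, "features.csv"), "\n")
cat("Example row (selected columns):\n")
print(round(feats[1, c("FO_mean", "SHAPE_volume", "GLRLM_RP",
                       "HH_GLCM_GLN")], 3))
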