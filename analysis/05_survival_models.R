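#!/usr/bin/env Rscript
# Supervised arm: 10-fold cross-validated Cox models per endpoint for
# radiomics-only, clinical-only and combined feature sets; Harrell
# c-index on train and held-out folds, paired comparison of clinical vs
# combined, and export of the final OS model as a nomogram table.
source("analysis/00_config.R")

feats <- read.csv(file.path(OUT, "features.csv"))
cohort <- read_cohort_csv(file.path(OUT, "cohort.csv"))
stable <- readLines(file.path(OUT, "stable_features.txt"))
X <- as.matrix(feats[, intersect(stable, names(feats)), drop = FALSE])

rows <- list()
for (ep in c("os", "dfs", "lc", "dc")) {
  reps <- lapply(c(radiomics = "radiomics", clinical = "clinical",
                   both = "both"), function(fs)
    cv_evaluate(cohort, X, endpoint = ep, feature_set = fs,
                n_folds = 10, seed = MASTER_SEED))
  for (fs in names(reps)) {
    r <- reps[[fs]]
    cstr <- function(m, ci) {
      if (!is.finite(m)) "/" else sprintf("%.3f [%.3f %.3f]", m, ci[1],
                                          ci[2])
    }
    cat(sprintf("%-4s %-9s train %s | test %s%s\n", ep, fs,
                cstr(r$train_mean, r$train_ci),
                cstr(r$test_mean, r$test_ci),
                if (r$no_model) "  (no model can be established)" else ""))
    rows[[paste(ep, fs)]] <- data.frame(
      endpoint = ep, feature_set = fs, no_model = r$no_model,
      train_c = r$train_mean, train_lo = r$train_ci[1],
      train_hi = r$train_ci[2], test_c = r$test_mean,
      test_lo = r$test_ci[1], test_hi = r$test_ci[2])
  }
  cmp <- tryCatch(compare_models(reps$clinical, reps$both),
                  error = function(e) NULL)
  if (!is.null(cmp))
    cat(sprintf("  paired t, clinical vs both (test folds): diff %.3f, p = %.3f\n",
                cmp$mean_difference, cmp$p_value))
  if (ep == "os" && length(reps$both$final_variables) > 0) {
    nom <- export_linear_predictor(reps$both$final_fit,
                                   reps$both$final_data)
    write.csv(nom$points, file.path(OUT, "nomogram_points_os.csv"),
              row.names = FALSE)
    write.csv(nom$survival, file.path(OUT, "nomogram_survival_os.csv"),
              row.names = FALSE)
    cat("  final OS model:", paste(reps$both$final_variables,
                                   collapse = ", "), "\n")
  }
}
write.csv(do.call(rbind, rows), file.path(OUT, "cv_report.csv"),
          row.names = FALSE)
cat("CV report:", file.path(OUT, "cv_report.csv"), "\n")
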