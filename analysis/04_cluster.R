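#!/usr/bin/env Rscript
# Unsupervised arm: NMF consensus clustering of the stable features,
# rank survey over 2..4 with 20 random restarts, chi-square tests of the
# cluster labels against clinical covariates, and Kaplan-Meier curves
# with a log-rank test for overall survival.
source("analysis/00_config.R")

feats <- read.csv(file.path(OUT, "features.csv"))
cohort <- read_cohort_csv(file.path(OUT, "cohort.csv"))
stable <- readLines(file.path(OUT, "stable_features.txt"))

X <- minmax_scale(as.matrix(feats[, intersect(stable, names(feats)),
                                  drop = FALSE]))
X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
cat("Clustering", nrow(X), "patients on", ncol(X), "stable features\n")

survey <- rank_survey(X, ranks = 2:4, n_restarts = 20, seed = MASTER_SEED)
print(survey$survey)
cat("Chosen rank:", survey$chosen_rank, "\n")
labels <- assign_clusters(survey)
cat("Cluster sizes:", table(labels), "\n")

chi <- cluster_vs_clinical(labels, cohort[, c("sex", "cT", "cN",
                                              "age_group")])
print(chi)
km <- km_logrank(labels, cohort, "os")
cat(sprintf("Log-rank (OS) between clusters: chisq %.2f, p = %.3f\n",
            km$statistic, km$p_value))

write.csv(data.frame(patient_id = cohort$patient_id, cluster = labels),
          file.path(OUT, "cluster_labels.csv"), row.names = FALSE)
write.csv(survey$survey, file.path(OUT, "rank_survey.csv"),
          row.names = FALSE)
write.csv(chi, file.path(OUT, "chisq_clinical.csv"), row.names = FALSE)
consensus_plot(survey, file.path(OUT, "consensus_map.png"))
km_plot(km, file.path(OUT, "km_clusters.png"))
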