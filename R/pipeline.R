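#' Read and validate a pipeline run configuration
#'
#' YAML with the keys below (all optional, defaults shown by
#' [default_run_config()]); unknown keys are rejected before any
#' computation. All stage randomness derives from the single `seed`.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("run config: unknown key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  stopifnot(cfg$rho_min > 0, cfg$rho_min < 1,
            cfg$volume_rho_max > 0, cfg$volume_rho_max <= 1,
            cfg$corr_threshold > 0, cfg$corr_threshold <= 1,
            cfg$alpha > 0, cfg$alpha <= 1,
            cfg$n_bins >= 2, cfg$folds >= 2, cfg$restarts >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    out_dir = "results/pipeline_run",
    seed = 1L,
    # phantom cohort
    n_patients = 40L, n_retest = 12L, n_recontour = 12L,
    grid_shape = 32L, tumor_radius_mm = c(12, 10, 9),
    tumor_radius_rel_range = c(0.6, 1.2),
    corr_length_range_mm = c(1.5, 6), texture_sd = 30, noise_sd = 10,
    boundary_sd_mm = 1,
    # survival generator
    radiomic_effect = -0.6, censor_rate = 0.3,
    # extraction / selection / modeling
    n_bins = 128L, rho_min = 0.7, volume_rho_max = 0.8,
    corr_threshold = 0.95, alpha = 0.05, folds = 10L,
    ranks = 2:4, restarts = 20L,
    endpoints = c("os")
  )
}

#' Run the whole study pipeline
#'
#' Orchestrates the stages in study order: simulate a phantom cohort
#' (with retest and recontour sub-studies) -> extract the feature bank ->
#' stability selection -> NMF consensus clustering with chi-square and
#' Kaplan-Meier/log-rank read-outs -> cross-validated Cox modeling per
#' endpoint. Writes feature tables, the stability report, cluster
#' labels, the chi-square table, KM and consensus figures, the CV report
#' and a machine-readable run log (seeds, parameters, package version)
#' into `config$out_dir`. Reruns with the same config are reproducible.
#'
#' @param config a `run_config` (from [read_run_config()]) or a path to
#'   a YAML config.
#' @return invisibly, the run directory; a `run_log.json` inside links
#'   every output to the config and seed.
#' @export
run_pipeline <- function(config = read_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(package_version = as.character(utils::packageVersion("ctradiomics")),
              r_version = R.version.string,
              config = unclass(cfg), stages = list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log$stages[[name]] <<- list(seconds = as.numeric(Sys.time() - t0,
                                                     units = "secs"))
    out
  }

  # --- simulate: per-patient texture heterogeneity drives both features
  # (via the phantom texture) and hazard (via the cohort generator)
  sim <- stage("simulate", {
    set.seed(cfg$seed)
    cl <- stats::runif(cfg$n_patients, cfg$corr_length_range_mm[1],
                       cfg$corr_length_range_mm[2])
    # tumor sizes vary across patients (the stability filter's volume
    # criterion is vacuous on a constant-size cohort)
    radii <- lapply(seq_len(cfg$n_patients), function(i)
      cfg$tumor_radius_mm * stats::runif(3, cfg$tumor_radius_rel_range[1],
                                         cfg$tumor_radius_rel_range[2]))
    phantoms <- lapply(seq_len(cfg$n_patients), function(i) {
      make_phantom(phantom_spec(
        grid_shape = cfg$grid_shape, tumor_radius_mm = radii[[i]],
        texture_corr_length_mm = cl[i], texture_sd = cfg$texture_sd,
        noise_sd = cfg$noise_sd, seed = cfg$seed * 1000L + i))
    })
    names(phantoms) <- sprintf("P%04d", seq_len(cfg$n_patients))
    z <- scale(cl)[, 1]
    cspec <- cohort_spec(n_patients = cfg$n_patients,
                         radiomic_effect = cfg$radiomic_effect,
                         censor_rate = cfg$censor_rate,
                         seed = cfg$seed + 7L)
    cohort <- simulate_cohort(cspec, texture = z)
    write_cohort_csv(cohort, file.path(cfg$out_dir, "cohort.csv"))
    list(phantoms = phantoms, cohort = cohort, corr_lengths = cl,
         radii = radii)
  })

  # --- extract
  feats <- stage("extract", {
    ft <- extract_cohort_features(sim$phantoms)
    utils::write.csv(cbind(patient_id = rownames(ft), ft),
                     file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
    ft
  })

  # --- stability: retest and recontour sub-studies on the first subjects
  stab <- stage("stability", {
    idx_rt <- seq_len(min(cfg$n_retest, cfg$n_patients))
    rt <- lapply(idx_rt, function(i) {
      make_retest_pair(phantom_spec(
        grid_shape = cfg$grid_shape, tumor_radius_mm = sim$radii[[i]],
        texture_corr_length_mm = sim$corr_lengths[i],
        texture_sd = cfg$texture_sd, noise_sd = cfg$noise_sd,
        seed = cfg$seed * 1000L + i),
        perturb = list(noise_sd = cfg$noise_sd))
    })
    f_a <- extract_cohort_features(lapply(rt, `[[`, "scan1"))
    f_b <- extract_cohort_features(lapply(rt, `[[`, "scan2"))
    vol_a <- f_a$roi_volume
    rep_rt <- run_stability(f_a[, -ncol(f_a)], f_b[, -ncol(f_b)], vol_a,
                            cfg$rho_min, cfg$volume_rho_max, "retest")
    idx_rc <- seq_len(min(cfg$n_recontour, cfg$n_patients))
    f_c1 <- f_c2 <- vector("list", length(idx_rc))
    for (i in idx_rc) {
      ph <- sim$phantoms[[i]]
      m2 <- make_recontour_pair(ph$volume, ph$mask, cfg$boundary_sd_mm,
                                seed = cfg$seed * 2000L + i)
      f_c1[[i]] <- list(volume = ph$volume, mask = ph$mask)
      f_c2[[i]] <- list(volume = ph$volume, mask = m2)
    }
    g_a <- extract_cohort_features(f_c1)
    g_b <- extract_cohort_features(f_c2)
    rep_rc <- run_stability(g_a[, -ncol(g_a)], g_b[, -ncol(g_b)],
                            g_a$roi_volume,
                            cfg$rho_min, cfg$volume_rho_max, "recontour")
    selected <- combine_selections(rep_rt, rep_rc)
    rep_all <- data.frame(feature = rep_rt$feature,
                          rho_retest = rep_rt$rho_pair,
                          rho_recontour = rep_rc$rho_pair,
                          rho_volume = rep_rt$rho_volume,
                          selected = rep_rt$feature %in% selected)
    utils::write.csv(rep_all, file.path(cfg$out_dir, "stability_report.csv"),
                     row.names = FALSE)
    stability_distribution_plot(list(retest = rep_rt, recontour = rep_rc),
                                file.path(cfg$out_dir, "stability_rho.png"))
    list(selected = selected, retest = rep_rt, recontour = rep_rc)
  })

  sel_feats <- stab$selected
  if (length(sel_feats) < 2L) {
    # fall back to reproducible features from the retest arm alone so the
    # downstream arms remain runnable on very small demo cohorts
    sel_feats <- stab$retest$feature[stab$retest$selected]
  }
  X <- as.matrix(feats[, intersect(sel_feats, colnames(feats)), drop = FALSE])
  if (ncol(X) < 3L)
    stop("pipeline: fewer than 3 stable features selected; enlarge the ",
         "retest/recontour sub-studies or relax the thresholds")

  # --- cluster
  clus <- stage("cluster", {
    Xs <- minmax_scale(X)
    keep <- apply(Xs, 2, function(x) stats::sd(x) > 0)
    survey <- rank_survey(Xs[, keep, drop = FALSE], ranks = cfg$ranks,
                          n_restarts = cfg$restarts, seed = cfg$seed)
    labels <- assign_clusters(survey)
    utils::write.csv(data.frame(patient_id = sim$cohort$patient_id,
                                cluster = labels),
                     file.path(cfg$out_dir, "cluster_labels.csv"),
                     row.names = FALSE)
    utils::write.csv(survey$survey, file.path(cfg$out_dir, "rank_survey.csv"),
                     row.names = FALSE)
    chi <- cluster_vs_clinical(labels,
                               sim$cohort[, c("sex", "cT", "cN", "age_group")])
    utils::write.csv(chi, file.path(cfg$out_dir, "chisq_clinical.csv"),
                     row.names = FALSE)
    consensus_plot(survey, file.path(cfg$out_dir, "consensus_map.png"))
    km <- km_logrank(labels, sim$cohort, cfg$endpoints[1])
    km_plot(km, file.path(cfg$out_dir, "km_clusters.png"))
    list(survey = survey, labels = labels, chi = chi, km = km)
  })

  # --- model
  stage("model", {
    rows <- list()
    for (ep in cfg$endpoints) {
      reps <- lapply(c("radiomics", "clinical", "both"), function(fs) {
        cv_evaluate(sim$cohort, features = X, endpoint = ep,
                    feature_set = fs, n_folds = cfg$folds,
                    seed = cfg$seed, alpha = cfg$alpha,
                    corr_threshold = cfg$corr_threshold)
      })
      names(reps) <- c("radiomics", "clinical", "both")
      for (fs in names(reps)) {
        r <- reps[[fs]]
        rows[[paste(ep, fs)]] <- data.frame(
          endpoint = ep, feature_set = fs, no_model = r$no_model,
          train_c = r$train_mean, train_lo = r$train_ci[1],
          train_hi = r$train_ci[2], test_c = r$test_mean,
          test_lo = r$test_ci[1], test_hi = r$test_ci[2])
      }
      cmp <- tryCatch(compare_models(reps$clinical, reps$both),
                      error = function(e) NULL)
      if (!is.null(cmp))
        rows[[paste(ep, "cmp")]] <- data.frame(
          endpoint = ep, feature_set = "both_vs_clinical",
          no_model = NA, train_c = NA, train_lo = NA, train_hi = NA,
          test_c = cmp$mean_difference, test_lo = NA,
          test_hi = cmp$p_value)
      fin <- reps$both
      if (!fin$no_model && length(fin$final_variables) > 0) {
        nom <- export_linear_predictor(fin$final_fit, fin$final_data)
        utils::write.csv(nom$points,
                         file.path(cfg$out_dir,
                                   sprintf("nomogram_points_%s.csv", ep)),
                         row.names = FALSE)
        utils::write.csv(nom$survival,
                         file.path(cfg$out_dir,
                                   sprintf("nomogram_survival_%s.csv", ep)),
                         row.names = FALSE)
      }
    }
    cvtab <- do.call(rbind, rows)
    utils::write.csv(cvtab, file.path(cfg$out_dir, "cv_report.csv"),
                     row.names = FALSE)
    cvtab
  })

  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(cfg$out_dir)
}
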