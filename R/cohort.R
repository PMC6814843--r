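#' Cohort simulation specification
#'
#' Parameters of the synthetic survival cohort: a Weibull proportional-
#' hazards model whose log-hazard is a linear combination of discrete
#' clinical covariates and a latent per-patient texture-heterogeneity
#' parameter, with uniform administrative censoring.
#'
#' @param n_patients cohort size (>= 2).
#' @param clinical_effects named numeric vector of log-hazard coefficients
#'   for clinical dummy columns (names as produced by
#'   [simulate_clinical()]: `sexM`, `cT4`, `cN1`, `cN2`, `age_gt60`);
#'   unnamed covariates get coefficient 0.
#' @param radiomic_effect log-hazard coefficient of the latent texture
#'   parameter.
#' @param baseline_shape,baseline_median Weibull shape and the baseline
#'   median survival in months (scale derived from it); defaults emulate a
#'   locally advanced rectal-cancer cohort (median OS ~ 60 months).
#' @param censor_rate administrative censoring fraction in [0, 1).
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 200L,
                        clinical_effects = c(sexM = 0.2, cT4 = 0.4,
                                             cN1 = 0.25, cN2 = 0.5,
                                             age_gt60 = 0.3),
                        radiomic_effect = 0,
                        baseline_shape = 1.2,
                        baseline_median = 60,
                        censor_rate = 0.3,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stop("cohort_spec: n_patients must be >= 2")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("cohort_spec: censor_rate must be in [0, 1)")
  structure(list(n_patients = n_patients,
                 clinical_effects = clinical_effects,
                 radiomic_effect = radiomic_effect,
                 baseline_shape = baseline_shape,
                 baseline_median = baseline_median,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw discrete clinical covariates
#'
#' Marginals loosely mirror a locally advanced rectal-cancer population:
#' ~2/3 male, mostly cT3, nodal involvement common. Assumes the RNG is
#' seeded by the caller.
#'
#' @param n number of patients.
#' @return data.frame with factors `sex`, `cT`, `cN`, `age_group`.
#' @export
simulate_clinical <- function(n) {
  data.frame(
    sex = factor(sample(c("F", "M"), n, TRUE, c(0.32, 0.68)),
                 levels = c("F", "M")),
    cT = factor(sample(c("T3", "T4"), n, TRUE, c(0.8, 0.2)),
                levels = c("T3", "T4")),
    cN = factor(sample(c("N0", "N1", "N2"), n, TRUE, c(0.3, 0.45, 0.25)),
                levels = c("N0", "N1", "N2")),
    age_group = factor(sample(c("le60", "gt60"), n, TRUE, c(0.55, 0.45)),
                       levels = c("le60", "gt60"))
  )
}

# dummy-code the clinical frame; column names match cohort_spec effects
clinical_dummies <- function(clinical) {
  mm <- stats::model.matrix(~ ., clinical)[, -1, drop = FALSE]
  colnames(mm) <- sub("^sex", "sex", colnames(mm))
  colnames(mm) <- sub("^cT", "cT", colnames(mm))
  colnames(mm) <- sub("^cN", "cN", colnames(mm))
  colnames(mm) <- sub("^age_group", "age_", colnames(mm))
  colnames(mm)[colnames(mm) == "age_gt60"] <- "age_gt60"
  mm
}

# Weibull PH: h(t) = lambda * k * t^(k-1) * exp(lp); inverse-CDF draw
weibull_ph_times <- function(lp, shape, median_baseline) {
  lambda <- log(2) / median_baseline^shape
  u <- stats::runif(length(lp))
  (-log(u) / (lambda * exp(lp)))^(1 / shape)
}

# administrative censoring: C ~ Unif(0, tau) with tau calibrated so that
# the expected censored fraction matches `rate`, given the drawn times
censor_times <- function(times, rate) {
  n <- length(times)
  if (rate == 0) return(rep(Inf, n))
  uc <- stats::runif(n)
  frac <- function(tau) mean(times > uc * tau) - rate
  hi <- max(times) * 2
  if (frac(hi) > 0) return(uc * hi)  # cannot censor less; best effort
  tau <- stats::uniroot(frac, c(1e-8, hi))$root
  uc * tau
}

#' Simulate a survival cohort with a latent texture phenotype
#'
#' Survival times for four endpoints (OS, DFS, LC, DC) are drawn from a
#' Weibull proportional-hazards model with
#' log-hazard = clinical_effects . dummies + radiomic_effect * texture,
#' then administratively censored. Endpoints share the linear predictor
#' but have independent baseline draws and endpoint-specific baseline
#' medians (LC slowest, DFS fastest).
#'
#' @param spec a [cohort_spec()].
#' @param texture numeric vector, one latent texture-heterogeneity value
#'   per patient (e.g. a correlation length or a phenotype indicator).
#' @return data.frame of class `survival_cohort`: `patient_id`, clinical
#'   factors, `texture`, and `time_<ep>`/`event_<ep>` for
#'   ep in os, dfs, lc, dc.
#' @export
simulate_cohort <- function(spec, texture) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  if (length(texture) != n)
    stop("simulate_cohort: need one texture value per patient (",
         length(texture), " != ", n, ")")
  set.seed(spec$seed)
  clinical <- simulate_clinical(n)
  mm <- clinical_dummies(clinical)
  beta <- stats::setNames(rep(0, ncol(mm)), colnames(mm))
  known <- intersect(names(spec$clinical_effects), names(beta))
  beta[known] <- spec$clinical_effects[known]
  lp <- as.vector(mm %*% beta) + spec$radiomic_effect * texture
  if (any(!is.finite(lp)))
    stop("simulate_cohort: non-finite log-hazard (check effects/texture)")
  med <- c(os = 1, dfs = 0.75, lc = 1.4, dc = 1.2) * spec$baseline_median
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)), clinical,
                    texture = texture)
  for (ep in names(med)) {
    tt <- weibull_ph_times(lp, spec$baseline_shape, med[[ep]])
    cc <- censor_times(tt, spec$censor_rate)
    out[[paste0("time_", ep)]] <- pmin(tt, cc)
    out[[paste0("event_", ep)]] <- as.integer(tt <= cc)
  }
  class(out) <- c("survival_cohort", "data.frame")
  out
}

#' Simulate a feature-level radiomics cohort
#'
#' Generates the objects the clustering and modeling arms consume without
#' going through image synthesis: a latent texture phenotype per patient,
#' a radiomics feature matrix in which `n_informative` features load on
#' the phenotype (the rest are noise), clinical covariates, and survival
#' endpoints whose hazard depends on both. Used for replicate-level
#' recovery and calibration studies where full phantom rendering would
#' add nothing but runtime.
#'
#' @param n_patients cohort size.
#' @param n_features total feature count.
#' @param n_informative number of features that load on the phenotype.
#' @param phenotype `"binary"` (two groups, +/- 0.5) or `"continuous"`
#'   (standard normal).
#' @param separation feature-space shift per unit phenotype, in feature-sd
#'   units.
#' @param radiomic_effect,clinical_effects,censor_rate,seed passed to
#'   [cohort_spec()].
#' @return list(features = matrix, cohort = `survival_cohort`,
#'   phenotype = numeric).
#' @export
simulate_feature_cohort <- function(n_patients = 120L, n_features = 40L,
                                    n_informative = 10L,
                                    phenotype = c("binary", "continuous"),
                                    separation = 2,
                                    radiomic_effect = 0,
                                    clinical_effects = c(sexM = 0.2, cT4 = 0.4,
                                                         cN1 = 0.25, cN2 = 0.5,
                                                         age_gt60 = 0.3),
                                    censor_rate = 0.3, seed = 1L) {
  phenotype <- match.arg(phenotype)
  set.seed(seed)
  z <- if (phenotype == "binary")
    sample(c(-0.5, 0.5), n_patients, TRUE)
  else stats::rnorm(n_patients)
  X <- matrix(stats::rnorm(n_patients * n_features), n_patients, n_features)
  n_informative <- min(n_informative, n_features)
  if (n_informative > 0) {
    sgn <- rep(c(1, -1), length.out = n_informative)  # mixed loading signs
    for (j in seq_len(n_informative))
      X[, j] <- X[, j] + separation * sgn[j] * z
  }
  colnames(X) <- sprintf("feat_%03d", seq_len(n_features))
  spec <- cohort_spec(n_patients = n_patients,
                      clinical_effects = clinical_effects,
                      radiomic_effect = radiomic_effect,
                      censor_rate = censor_rate,
                      seed = seed + 1L)
  cohort <- simulate_cohort(spec, texture = z)
  list(features = X, cohort = cohort, phenotype = z)
}

#' Write a cohort to CSV
#' @param cohort a `survival_cohort`; @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort_csv()]
#' @param path CSV file.
#' @return a `survival_cohort` data.frame.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = TRUE)
  class(out) <- c("survival_cohort", "data.frame")
  out
}
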