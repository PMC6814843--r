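#' Greedy correlation filter
#'
#' While any pair of columns has |Pearson r| above the threshold, drops
#' the member of the worst pair with the larger mean absolute correlation
#' to all remaining columns (ties keep the earlier column). Deterministic
#' given column order. Constant columns have undefined correlations and
#' are dropped first with a warning.
#'
#' @param X numeric matrix/data.frame (observations x features).
#' @param threshold |r| cutoff, default 0.95.
#' @return character vector of retained column names.
#' @export
correlation_filter <- function(X, threshold = 0.95) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(colnames(X))
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    warning("correlation_filter: dropping constant columns: ",
            paste(colnames(X)[!is.finite(sds) | sds == 0], collapse = ", "))
    X <- X[, is.finite(sds) & sds > 0, drop = FALSE]
    if (ncol(X) < 2L) return(colnames(X))
  }
  R <- abs(stats::cor(X, use = "pairwise.complete.obs"))
  diag(R) <- 0
  keep <- colnames(X)
  while (TRUE) {
    mx <- max(R, na.rm = TRUE)
    if (mx <= threshold) break
    w <- which(R == mx, arr.ind = TRUE)[1, ]
    i <- w[["row"]]; j <- w[["col"]]
    mi <- mean(R[i, -i]); mj <- mean(R[j, -j])
    drop_idx <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    keep <- keep[-drop_idx]
    R <- R[-drop_idx, -drop_idx, drop = FALSE]
    if (length(keep) < 2L) break
  }
  keep
}

#' Median imputation (train-fold statistics only)
#'
#' Fills missing entries with per-column medians. When `medians` is
#' supplied (computed on a training fold), those are used — never the
#' statistics of the data being imputed — so cross-validation folds
#' cannot leak.
#'
#' @param X data.frame/matrix with possible `NA`s.
#' @param medians optional named numeric vector of imputation values.
#' @return data.frame with no `NA`s and attribute `medians`.
#' @export
impute_missing <- function(X, medians = NULL) {
  X <- as.data.frame(X)
  if (is.null(medians)) {
    medians <- vapply(X, function(x) stats::median(x, na.rm = TRUE), 0)
    if (any(is.na(medians)))
      stop("impute_missing: column(s) entirely missing: ",
           paste(names(medians)[is.na(medians)], collapse = ", "))
  }
  for (v in names(X)) {
    miss <- is.na(X[[v]])
    if (any(miss)) X[[v]][miss] <- medians[[v]]
  }
  attr(X, "medians") <- medians
  X
}

#' Univariate survival screen
#'
#' Tests each candidate against the endpoint: discrete variables
#' (factor/character/logical, or numeric flagged in `discrete`) by the
#' log-rank test across their categories, continuous variables by the
#' Wald test of a single-variable Cox model. Keeps p < alpha. Variables
#' with a single category are skipped with a warning.
#'
#' @param data data.frame of candidate variables.
#' @param time,event survival outcome vectors.
#' @param alpha significance level (default 0.05).
#' @param discrete names of columns to treat as discrete regardless of
#'   storage type.
#' @return character vector of selected names; attribute `p_values`.
#' @export
univariate_screen <- function(data, time, event, alpha = 0.05,
                              discrete = character(0)) {
  stopifnot(nrow(data) == length(time), length(time) == length(event))
  pvals <- vapply(names(data), function(v) {
    x <- data[[v]]
    is_disc <- v %in% discrete || is.factor(x) || is.character(x) ||
      is.logical(x)
    if (is_disc) {
      x <- factor(x)
      if (nlevels(droplevels(x)) < 2L) {
        warning("univariate_screen: ", v, " has one category; skipped")
        return(NA_real_)
      }
      sd_ <- try(survival::survdiff(
        survival::Surv(time, event) ~ x), silent = TRUE)
      if (inherits(sd_, "try-error")) return(NA_real_)
      stats::pchisq(sd_$chisq, length(sd_$n) - 1, lower.tail = FALSE)
    } else {
      if (stats::sd(x, na.rm = TRUE) == 0 || !any(is.finite(x))) {
        warning("univariate_screen: ", v, " is constant; skipped")
        return(NA_real_)
      }
      ft <- try(survival::coxph(survival::Surv(time, event) ~ x,
                                ties = "breslow"), silent = TRUE)
      if (inherits(ft, "try-error")) return(NA_real_)
      summary(ft)$coefficients[1, "Pr(>|z|)"]
    }
  }, 0)
  sel <- names(pvals)[!is.na(pvals) & pvals < alpha]
  attr(sel, "p_values") <- pvals
  sel
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood with Breslow tie handling (ties are common
#' after discretization). An empty variable set gives the null model.
#'
#' @param data data.frame holding the variables.
#' @param time,event outcome vectors.
#' @param variables character vector of column names (possibly empty).
#' @return list of class `cox_fit`: `coefficients`, `se`, `loglik`
#'   (fitted model log partial likelihood), `loglik_null`, `aic`
#'   (penalty k = 2), `fit` (the underlying [survival::coxph] object,
#'   `NULL` for the null model), `variables`.
#' @export
cox_fit <- function(data, time, event, variables) {
  sv <- survival::Surv(time, event)
  if (length(variables) == 0L) {
    ft <- survival::coxph(sv ~ 1, ties = "breslow")
    ll <- ft$loglik[1]
    return(structure(list(coefficients = numeric(0), se = numeric(0),
                          loglik = ll, loglik_null = ll, aic = -2 * ll,
                          fit = NULL, variables = character(0)),
                     class = "cox_fit"))
  }
  df <- data[, variables, drop = FALSE]
  df$.time <- time; df$.event <- event
  fml <- stats::reformulate(sprintf("`%s`", variables),
                            response = "survival::Surv(.time, .event)")
  ft <- survival::coxph(fml, data = df, ties = "breslow")
  if (any(is.na(stats::coef(ft)))) {
    bad <- names(stats::coef(ft))[is.na(stats::coef(ft))]
    stop("cox_fit: inestimable coefficient(s) (separation/collinearity): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(ft)
  structure(list(coefficients = stats::coef(ft),
                 se = sm$coefficients[, "se(coef)"],
                 loglik = ft$loglik[2], loglik_null = ft$loglik[1],
                 aic = -2 * ft$loglik[2] + 2 * length(stats::coef(ft)),
                 fit = ft, variables = variables),
            class = "cox_fit")
}

#' Backward stepwise selection by AIC
#'
#' Starting from the joint fit of all candidates, repeatedly removes the
#' variable whose removal most decreases AIC = -2 logPL + k |variables|;
#' stops when no removal decreases it. The conventional penalty is k = 2;
#' `k = 1` is also accepted. If the initial joint fit fails, the
#' candidate with the worst univariate p-value is dropped and the fit
#' retried (with a warning).
#'
#' @param data,time,event as in [cox_fit()].
#' @param candidates character vector of candidate variables.
#' @param k AIC penalty per parameter (default 2).
#' @return list: `variables`, `fit` (a `cox_fit`), `aic`, `path`
#'   (data.frame of the removal sequence).
#' @export
backward_stepwise <- function(data, time, event, candidates, k = 2) {
  aic_of <- function(ft) -2 * ft$loglik + k * length(ft$coefficients)
  vars <- candidates
  cur <- NULL
  while (is.null(cur)) {
    cur <- tryCatch(cox_fit(data, time, event, vars), error = function(e) NULL)
    if (is.null(cur)) {
      if (length(vars) == 0L) stop("backward_stepwise: even the null fit failed")
      ps <- attr(univariate_screen(data[, vars, drop = FALSE], time, event,
                                   alpha = 1.01), "p_values")
      worst <- names(ps)[which.max(ps)]
      warning("backward_stepwise: joint fit failed; dropping ", worst)
      vars <- setdiff(vars, worst)
    }
  }
  path <- data.frame(removed = "<start>", aic = aic_of(cur))
  repeat {
    if (length(vars) == 0L) break
    trials <- lapply(vars, function(v) {
      tryCatch(cox_fit(data, time, event, setdiff(vars, v)),
               error = function(e) NULL)
    })
    aics <- vapply(trials, function(ft) if (is.null(ft)) Inf else aic_of(ft), 0)
    best <- which.min(aics)
    if (aics[best] >= aic_of(cur)) break
    path <- rbind(path, data.frame(removed = vars[best], aic = aics[best]))
    cur <- trials[[best]]
    vars <- setdiff(vars, vars[best])
  }
  list(variables = vars, fit = cur, aic = aic_of(cur), path = path)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering
#' agrees with the observed survival ordering. A pair is comparable when
#' the earlier observed time is an event; tied risks count 0.5. 0.5 is
#' chance level, 1 perfect ranking.
#'
#' @param risk predicted risk scores (higher = earlier event expected).
#' @param time,event outcome vectors.
#' @return scalar in [0, 1].
#' @export
harrell_cindex <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  ok <- is.finite(risk) & is.finite(time)
  risk <- risk[ok]; time <- time[ok]; event <- event[ok]
  n <- length(risk)
  if (n < 2L) stop("harrell_cindex: no usable pairs")
  comp <- outer(time, time, "<") & matrix(event == 1, n, n)
  if (!any(comp)) stop("harrell_cindex: no comparable pairs under censoring")
  dr <- outer(risk, risk, "-")
  conc <- sum(comp & (dr > 0))
  ties <- sum(comp & (dr == 0))
  (conc + 0.5 * ties) / sum(comp)
}

# stratified-by-event fold assignment
make_folds <- function(event, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(event))
  for (g in unique(event)) {
    idx <- sample(which(event == g))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated Cox modeling of one endpoint
#'
#' The 10-fold strategy: folds are random but stratified by the event
#' indicator; within each training fold, continuous features pass a
#' |r| > 0.95 correlation filter, missing values are median-imputed with
#' training-fold medians, candidates pass the univariate screen
#' (log-rank for discrete, Cox Wald for continuous, p < alpha), the
#' survivors are reduced by backward-stepwise AIC, and the resulting
#' model is fit on the training fold. Harrell's c-index is computed on
#' the training and the held-out fold. When a majority of folds select no
#' variable, the endpoint/feature-set combination is reported as
#' "no model can be established". A final model on all data (same steps)
#' is also returned.
#'
#' @param cohort a `survival_cohort` data.frame (clinical factors +
#'   endpoints).
#' @param features numeric matrix/data.frame of radiomics features, rows
#'   aligned with `cohort` (may be `NULL` for the clinical set).
#' @param endpoint `"os"`, `"dfs"`, `"lc"` or `"dc"`.
#' @param feature_set `"radiomics"`, `"clinical"` or `"both"`.
#' @param n_folds folds (default 10); @param seed fold seed.
#' @param alpha screen level; @param corr_threshold filter cutoff;
#' @param aic_k stepwise penalty.
#' @param clinical_vars names of the discrete clinical covariates.
#' @return list of class `cv_model_report`: `per_fold` data.frame,
#'   `train_mean`/`train_ci`, `test_mean`/`test_ci`, `no_model`,
#'   `final_variables`, `final_fit`, `folds`, plus the call parameters.
#' @export
cv_evaluate <- function(cohort, features = NULL, endpoint = "os",
                        feature_set = c("both", "clinical", "radiomics"),
                        n_folds = 10L, seed = 1L, alpha = 0.05,
                        corr_threshold = 0.95, aic_k = 2,
                        clinical_vars = c("sex", "cT", "cN", "age_group")) {
  feature_set <- match.arg(feature_set)
  tcol <- paste0("time_", endpoint); ecol <- paste0("event_", endpoint)
  stopifnot(all(c(tcol, ecol) %in% names(cohort)))
  time <- cohort[[tcol]]; event <- cohort[[ecol]]
  if (sum(event) < n_folds)
    stop("cv_evaluate: need at least one event per fold (",
         sum(event), " events, ", n_folds, " folds)")

  clin <- NULL
  if (feature_set %in% c("clinical", "both")) {
    cv_present <- intersect(clinical_vars, names(cohort))
    clin <- as.data.frame(clinical_dummies(cohort[, cv_present, drop = FALSE]))
  }
  rad <- if (feature_set %in% c("radiomics", "both") && !is.null(features))
    as.data.frame(features) else NULL
  if (feature_set %in% c("radiomics", "both") && is.null(rad))
    stop("cv_evaluate: feature_set ", feature_set,
         " requires a feature matrix")
  discrete_vars <- if (is.null(clin)) character(0) else names(clin)

  folds <- make_folds(event, n_folds, seed)
  fit_once <- function(train_idx) {
    vars_df <- list()
    if (!is.null(clin)) vars_df$clin <- clin
    if (!is.null(rad)) {
      kept <- correlation_filter(rad[train_idx, , drop = FALSE],
                                 corr_threshold)
      r_tr <- impute_missing(rad[train_idx, kept, drop = FALSE])
      r_all <- impute_missing(rad[, kept, drop = FALSE],
                              medians = attr(r_tr, "medians"))
      vars_df$rad <- r_all
    }
    dat <- do.call(cbind, unname(vars_df))
    cand <- univariate_screen(dat[train_idx, , drop = FALSE],
                              time[train_idx], event[train_idx],
                              alpha = alpha, discrete = discrete_vars)
    if (length(cand) == 0L)
      return(list(dat = dat, variables = character(0), fit = NULL))
    st <- backward_stepwise(dat[train_idx, , drop = FALSE],
                            time[train_idx], event[train_idx],
                            cand, k = aic_k)
    list(dat = dat, variables = st$variables, fit = st$fit)
  }

  per_fold <- data.frame(fold = seq_len(n_folds), n_selected = 0L,
                         train_c = NA_real_, test_c = NA_real_)
  sel_list <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (sum(event[te]) == 0L) next  # no comparable pairs possible
    res <- suppressWarnings(fit_once(tr))
    sel_list[[f]] <- res$variables
    per_fold$n_selected[f] <- length(res$variables)
    if (length(res$variables) == 0L) next
    lp <- as.vector(as.matrix(res$dat[, res$variables, drop = FALSE]) %*%
                      res$fit$coefficients)
    per_fold$train_c[f] <- harrell_cindex(lp[tr], time[tr], event[tr])
    per_fold$test_c[f] <- tryCatch(
      harrell_cindex(lp[te], time[te], event[te]), error = function(e) NA)
  }
  no_model <- sum(per_fold$n_selected == 0L) > n_folds / 2
  ci <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(c(NA, NA))
    mean(x) + c(-1, 1) * 1.96 * stats::sd(x) / sqrt(length(x))
  }
  final <- suppressWarnings(fit_once(seq_along(time)))
  structure(list(endpoint = endpoint, feature_set = feature_set,
                 per_fold = per_fold, fold_variables = sel_list,
                 train_mean = mean(per_fold$train_c, na.rm = TRUE),
                 train_ci = ci(per_fold$train_c),
                 test_mean = mean(per_fold$test_c, na.rm = TRUE),
                 test_ci = ci(per_fold$test_c),
                 no_model = no_model,
                 final_variables = final$variables,
                 final_fit = final$fit, final_data = final$dat,
                 folds = folds, seed = seed, alpha = alpha,
                 corr_threshold = corr_threshold, aic_k = aic_k),
            class = "cv_model_report")
}

#' @export
print.cv_model_report <- function(x, ...) {
  cat(sprintf("<cv_model_report> endpoint %s, %s features\n",
              x$endpoint, x$feature_set))
  if (x$no_model) {
    cat("  no model can be established (majority of folds selected nothing)\n")
  } else {
    cat(sprintf("  train c-index %.3f [%.3f %.3f]\n", x$train_mean,
                x$train_ci[1], x$train_ci[2]))
    cat(sprintf("  test  c-index %.3f [%.3f %.3f]\n", x$test_mean,
                x$test_ci[1], x$test_ci[2]))
    cat("  final model: ",
        if (length(x$final_variables)) paste(x$final_variables,
                                             collapse = ", ")
        else "(empty)", "\n", sep = "")
  }
  invisible(x)
}

#' Paired comparison of two cross-validated models
#'
#' Paired t-test across per-fold held-out c-indices (the fold partitions
#' must be identical). Identical per-fold values give p = 1; a nonzero
#' constant shift (zero-variance differences) is reported as p below
#' machine precision.
#'
#' @param report_a,report_b `cv_model_report`s on the same folds.
#' @return list: `statistic`, `p_value`, `mean_difference` (b - a),
#'   `n_folds`.
#' @export
compare_models <- function(report_a, report_b) {
  if (!identical(report_a$folds, report_b$folds))
    stop("compare_models: reports use different fold partitions")
  a <- report_a$per_fold$test_c; b <- report_b$per_fold$test_c
  ok <- !is.na(a) & !is.na(b)
  d <- (b - a)[ok]
  if (length(d) < 2L) stop("compare_models: fewer than 2 paired folds")
  if (stats::sd(d) < 1e-12) {
    return(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p_value = if (mean(d) == 0) 1 else 2e-16,
                mean_difference = mean(d), n_folds = length(d)))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = mean(d), n_folds = length(d))
}

#' Export a fitted Cox model as a nomogram table
#'
#' Linear-predictor point scales: each variable's contribution is mapped
#' to points, 100 points spanning the largest single-variable range, and
#' total points are mapped to predicted survival probabilities at the
#' requested horizons via the Breslow baseline hazard.
#'
#' @param fit a `cox_fit` with at least one variable.
#' @param data data.frame the model was fit on (for observed ranges).
#' @param horizons times at which to tabulate survival (default 12, 36,
#'   60).
#' @return list: `points` (data.frame variable/value/points),
#'   `survival` (data.frame total_points/linear_predictor and one column
#'   per horizon).
#' @export
export_linear_predictor <- function(fit, data, horizons = c(12, 36, 60)) {
  stopifnot(inherits(fit, "cox_fit"), length(fit$variables) > 0)
  beta <- fit$coefficients
  contrib <- lapply(fit$variables, function(v) {
    x <- data[[v]]
    vals <- if (length(unique(x)) <= 6) sort(unique(x))
      else seq(min(x), max(x), length.out = 5)
    data.frame(variable = v, value = vals,
               contribution = beta[[v]] * vals)
  })
  ranges <- vapply(contrib, function(d)
    max(d$contribution) - min(d$contribution), 0)
  scale <- 100 / max(ranges)
  points <- do.call(rbind, lapply(contrib, function(d) {
    d$points <- (d$contribution - min(d$contribution)) * scale
    d
  }))
  lp_obs <- as.vector(as.matrix(data[, fit$variables, drop = FALSE]) %*% beta)
  bh <- survival::basehaz(fit$fit, centered = TRUE)
  H0 <- function(t) {
    if (t <= min(bh$time)) return(0)
    max(bh$hazard[bh$time <= t])
  }
  lp_grid <- seq(min(lp_obs), max(lp_obs), length.out = 20)
  lp_centered <- lp_grid - mean(lp_obs)
  surv <- data.frame(total_points = (lp_grid - min(lp_grid)) * scale,
                     linear_predictor = lp_grid)
  for (h in horizons)
    surv[[sprintf("surv_%g", h)]] <- exp(-H0(h) * exp(lp_centered))
  list(points = points, survival = surv)
}
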