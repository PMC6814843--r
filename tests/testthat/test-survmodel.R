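test_that("correlation filter keeps one of an exact duplicate and follows the
           greedy rule on a constructed triple", {
  set.seed(1)
  x <- rnorm(200)
  X <- cbind(a = x, b = x, c = rnorm(200))
  expect_setequal(correlation_filter(X), c("a", "c"))  # earlier column kept
  # r(A,B)=r(A,C)~0.99, r(B,C)~0.98: greedy drops A (largest mean |r|),
  # then B~C still exceeds 0.95 -> one survivor
  A <- rnorm(4000)
  B <- A + rnorm(4000, 0, 0.13)
  C <- A + rnorm(4000, 0, 0.13)
  Y <- cbind(A = A, B = B, C = C)
  r <- abs(cor(Y))
  skip_if_not(r["A", "B"] > 0.98 && r["B", "C"] > 0.95)  # construction check
  expect_length(correlation_filter(Y), 1)
  # nothing above the threshold: everything retained
  set.seed(2)
  Z <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_setequal(correlation_filter(Z), c("x", "y", "z"))
})

test_that("correlation filter agrees with caret's findCorrelation on random
           feature sets", {
  skip_if_not_installed("caret")
  set.seed(5)
  n <- 150
  base <- matrix(rnorm(n * 4), n, 4)
  X <- cbind(base,
             base[, 1] + rnorm(n, 0, 0.1),
             base[, 2] + rnorm(n, 0, 0.05))
  colnames(X) <- paste0("v", 1:6)
  mine <- correlation_filter(X, 0.95)
  caret_drop <- caret::findCorrelation(cor(X), cutoff = 0.95, exact = TRUE)
  theirs <- setdiff(colnames(X), colnames(X)[caret_drop])
  expect_equal(length(mine), length(theirs))
})

test_that("median imputation uses training statistics only (no leakage)", {
  X <- data.frame(f = c(1, 3, 5, NA))
  expect_equal(impute_missing(X)$f[4], 3)
  expect_identical(impute_missing(data.frame(f = 1:4))$f, 1:4)
  # train values all below 0, test all above; a leaked median would be > 0
  train <- data.frame(f = c(-5, -3, NA, -1))
  tr_imp <- impute_missing(train)
  test <- data.frame(f = c(100, NA, 300))
  te_imp <- impute_missing(test, medians = attr(tr_imp, "medians"))
  expect_equal(te_imp$f[2], -3)
  expect_error(impute_missing(data.frame(f = c(NA_real_, NA))), "entirely")
})

test_that("univariate screen: alpha=1 passes all testable variables; single
           category skipped", {
  set.seed(3)
  n <- 60
  d <- data.frame(x = rnorm(n), g = factor(rep(c("a", "b"), n / 2)),
                  solo = factor(rep("a", n)))
  tt <- rexp(n); ev <- rbinom(n, 1, 0.8)
  expect_warning(sel <- univariate_screen(d, tt, ev, alpha = 1.01),
                 "one category")
  expect_setequal(sel, c("x", "g"))
})

test_that("screen has power against a variable equal to the true log-hazard", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    z <- rnorm(400)
    sp <- cohort_spec(n_patients = 400, clinical_effects = c(sexM = 0),
                      radiomic_effect = 1, seed = 900 + s)
    co <- simulate_cohort(sp, texture = z)
    "z" %in% univariate_screen(data.frame(z = z), co$time_os, co$event_os)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("null Cox partial likelihood matches the analytic Breslow value", {
  set.seed(8)
  n <- 30
  tt <- sample(1:10, n, TRUE)  # heavy ties
  ev <- rbinom(n, 1, 0.7)
  f0 <- cox_fit(data.frame(), tt, ev, character(0))
  # Breslow null: -sum over events of log(risk set size at event time)
  analytic <- -sum(vapply(which(ev == 1),
                          function(i) log(sum(tt >= tt[i])), 0))
  expect_equal(f0$loglik, analytic, tolerance = 1e-10)
})

test_that("Cox score test for a binary covariate equals the log-rank statistic", {
  set.seed(9)
  n <- 80
  g <- rep(0:1, n / 2)
  tt <- rexp(n, 0.1 * exp(0.5 * g))
  ev <- rbinom(n, 1, 0.85)
  ft <- survival::coxph(survival::Surv(tt, ev) ~ g, ties = "breslow")
  lr <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  expect_equal(unname(summary(ft)$sctest["test"]), lr$chisq,
               tolerance = 1e-6)
})

test_that("Cox coefficient recovery at n=2000 without censoring", {
  set.seed(10)
  n <- 2000
  x <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(0.7 * x))
  f <- cox_fit(data.frame(x = x), tt, rep(1, n), "x")
  expect_lt(abs(f$coefficients[["x"]] - 0.7), 0.1)
  expect_gt(f$loglik, f$loglik_null)
})

test_that("backward stepwise keeps a true predictor among noise and its AIC
           path never increases", {
  kept <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 1000
    d <- data.frame(true = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), n4 = rnorm(n), n5 = rnorm(n))
    tt <- rexp(n, 0.05 * exp(0.8 * d$true))
    ev <- rbinom(n, 1, 0.8)
    st <- backward_stepwise(d, tt, ev, names(d))
    stopifnot(all(diff(st$path$aic) <= 0))
    "true" %in% st$variables
  }, TRUE)
  expect_gte(mean(kept), 0.9)
})

test_that("empty candidate list yields the null model", {
  set.seed(11)
  st <- backward_stepwise(data.frame(x = rnorm(20)), rexp(20), rep(1, 20),
                          character(0))
  expect_length(st$variables, 0)
  expect_equal(st$aic, -2 * st$fit$loglik)
})

test_that("Harrell c-index: hand-enumerated 3-patient cases and antisymmetry", {
  expect_equal(harrell_cindex(c(0.9, 0.8, 0.1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrell_cindex(c(0.8, 0.9, 0.1), c(1, 2, 3), c(1, 1, 1)), 2 / 3)
  set.seed(12)
  n <- 200
  r <- rnorm(n); tt <- rexp(n); ev <- rbinom(n, 1, 0.6)
  expect_equal(harrell_cindex(-r, tt, ev), 1 - harrell_cindex(r, tt, ev))
  # censored patients can only enter as the later member of a pair
  expect_error(harrell_cindex(c(1, 2), c(1, 2), c(0, 0)), "comparable")
})

test_that("c-index agrees with survival::concordance", {
  set.seed(13)
  n <- 300
  r <- rnorm(n); tt <- rexp(n); ev <- rbinom(n, 1, 0.7)
  ours <- harrell_cindex(r, tt, ev)
  theirs <- survival::concordance(survival::Surv(tt, ev) ~ r)$concordance
  expect_equal(ours, 1 - theirs, tolerance = 1e-12)
})

test_that("cv_evaluate is deterministic given a seed and stratifies folds by
           event", {
  fc <- simulate_feature_cohort(n_patients = 120, radiomic_effect = 0.8,
                                seed = 17)
  r1 <- cv_evaluate(fc$cohort, fc$features, "os", "both", seed = 4)
  r2 <- cv_evaluate(fc$cohort, fc$features, "os", "both", seed = 4)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$folds, r2$folds)
  ev <- fc$cohort$event_os
  per_fold_events <- tapply(ev, r1$folds, sum)
  expect_lte(diff(range(per_fold_events)), 1)
})

test_that("cross-validation never uses held-out rows for fold statistics", {
  # marker construction: one feature column whose test-fold rows carry an
  # extreme value; if imputation or screening leaked, the training median
  # and selection would shift with them
  fc <- simulate_feature_cohort(n_patients = 100, radiomic_effect = 1,
                                n_features = 5, seed = 23)
  X <- fc$features
  r_ref <- cv_evaluate(fc$cohort, X, "os", "radiomics", seed = 9)
  fold1 <- which(r_ref$folds == 1)
  X2 <- X
  X2[fold1, ] <- X2[fold1, ] + 1e6  # poison held-out rows of fold 1
  r_poison <- cv_evaluate(fc$cohort, X2, "os", "radiomics", seed = 9)
  expect_identical(r_ref$fold_variables[[1]], r_poison$fold_variables[[1]])
  expect_equal(r_ref$per_fold$train_c[1], r_poison$per_fold$train_c[1])
})

test_that("pure-noise candidates exercise the no-model path", {
  set.seed(19)
  fc <- simulate_feature_cohort(n_patients = 80, n_features = 4,
                                n_informative = 0, radiomic_effect = 0,
                                clinical_effects = c(sexM = 0), seed = 77)
  r <- cv_evaluate(fc$cohort, fc$features, "os", "radiomics", seed = 2,
                   alpha = 0.001)  # nothing survives a strict screen
  expect_true(r$no_model)
  expect_true(all(r$per_fold$n_selected == 0))
})

test_that("compare_models: identical reports, constant shift, symmetry", {
  fc <- simulate_feature_cohort(n_patients = 120, radiomic_effect = 0.8,
                                seed = 29)
  r <- cv_evaluate(fc$cohort, fc$features, "os", "both", seed = 6)
  same <- compare_models(r, r)
  expect_equal(same$p_value, 1)
  r_shift <- r
  r_shift$per_fold$test_c <- r$per_fold$test_c + 0.05
  shift <- compare_models(r, r_shift)
  expect_lt(shift$p_value, 0.001)
  ab <- compare_models(r, r_shift); ba <- compare_models(r_shift, r)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$mean_difference, -ba$mean_difference)
  r_bad <- r; r_bad$folds <- rev(r$folds)
  expect_error(compare_models(r, r_bad), "fold partitions")
})

test_that("nomogram table ranks patients exactly as the raw coefficients do", {
  fc <- simulate_feature_cohort(n_patients = 150, radiomic_effect = 1,
                                seed = 37)
  r <- cv_evaluate(fc$cohort, fc$features, "os", "both", seed = 3)
  skip_if(length(r$final_variables) == 0)
  nom <- export_linear_predictor(r$final_fit, r$final_data)
  expect_true(all(c("variable", "value", "points") %in% names(nom$points)))
  # per-variable: higher contribution to risk = more points, monotone
  for (v in unique(nom$points$variable)) {
    pv <- nom$points[nom$points$variable == v, ]
    expect_true(all(diff(pv$points[order(pv$contribution)]) >= 0))
  }
  # point totals, read off the table by interpolation, rank 100 patients
  # exactly like the raw coefficients (each scale is linear in its value)
  set.seed(1)
  idx <- sample(nrow(r$final_data), 100)
  beta <- r$final_fit$coefficients
  lp <- as.vector(as.matrix(r$final_data[idx, r$final_variables,
                                         drop = FALSE]) %*% beta)
  pts <- rowSums(vapply(r$final_variables, function(v) {
    pv <- nom$points[nom$points$variable == v, ]
    stats::approx(pv$value, pv$points, xout = r$final_data[idx, v],
                  rule = 2)$y
  }, numeric(length(idx))))
  expect_gt(cor(lp, pts, method = "spearman"), 0.999)
  # binary single-variable model gives a two-row table
  d2 <- data.frame(b = rep(0:1, 50))
  tt <- rexp(100, 0.1 * exp(0.7 * d2$b))
  f2 <- cox_fit(d2, tt, rep(1, 100), "b")
  nom2 <- export_linear_predictor(f2, d2)
  expect_equal(nrow(nom2$points), 2)
  # survival probabilities decrease with total points at each horizon
  expect_true(all(diff(nom2$survival$surv_36) <= 0))
})
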