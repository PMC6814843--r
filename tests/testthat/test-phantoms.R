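test_that("zero-noise phantom has constant ROI intensity and is deterministic", {
  sp <- tiny_spec(seed = 5, texture_sd = 0, noise_sd = 0)
  ph <- make_phantom(sp)
  expect_true(all(ph$volume$data[ph$mask$data] == sp$mean_hu))
  ph2 <- make_phantom(sp)
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_identical(ph$mask$data, ph2$mask$data)
})

test_that("oversized tumors are rejected", {
  expect_error(phantom_spec(grid_shape = 16, spacing_mm = 1,
                            tumor_radius_mm = 10),
               "does not fit")
})

test_that("longer texture correlation length raises lag-1 autocorrelation", {
  ac <- sapply(1:20, function(s) {
    long <- make_phantom(tiny_spec(seed = s, texture_corr_length_mm = 8,
                                   noise_sd = 0))
    short <- make_phantom(tiny_spec(seed = s, texture_corr_length_mm = 1,
                                    noise_sd = 0))
    c(long = roi_lag1_autocor(long$volume, long$mask),
      short = roi_lag1_autocor(short$volume, short$mask))
  })
  expect_true(all(ac["long", ] > ac["short", ]))
})

test_that("retest pair: no perturbation gives identical scans", {
  pr <- make_retest_pair(tiny_spec(seed = 2), perturb = NULL)
  expect_identical(pr$scan1$volume$data, pr$scan2$volume$data)
  expect_identical(pr$scan1$mask$data, pr$scan2$mask$data)
})

test_that("retest pair under noise-only perturbation: same mask, close ROI means", {
  diffs <- vapply(1:100, function(s) {
    sp <- tiny_spec(seed = s)
    pr <- make_retest_pair(sp, perturb = list(noise_sd = sp$noise_sd))
    stopifnot(identical(pr$scan1$mask$data, pr$scan2$mask$data))
    m <- pr$scan1$mask$data
    n <- sum(m)
    abs(mean(pr$scan1$volume$data[m]) - mean(pr$scan2$volume$data[m])) /
      (sp$noise_sd / sqrt(n))
  }, 0)
  # means of two independent noise draws differ by sqrt(2)*sd/sqrt(n);
  # 3 sd/sqrt(n) is ~2.1 sigma of that difference
  expect_gte(mean(diffs < 3), 0.95)
})

test_that("recontour: zero boundary sd returns the identical mask with Dice 1", {
  ph <- make_phantom(tiny_spec(seed = 3))
  m2 <- make_recontour_pair(ph$volume, ph$mask, 0, seed = 1)
  expect_identical(m2$data, ph$mask$data)
  expect_equal(attr(m2, "dice"), 1)
})

test_that("recontour with sub-voxel boundary sd keeps Dice above 0.8", {
  # clinically sized tumor (semi-axes 16/14/12 mm): Dice loss at fixed
  # boundary sd scales with surface/volume, so the small test phantoms
  # elsewhere would understate overlap
  ph <- make_phantom(phantom_spec(seed = 4))
  dice <- vapply(1:50, function(s) {
    attr(make_recontour_pair(ph$volume, ph$mask, 1, seed = s), "dice")
  }, 0)
  expect_true(all(dice > 0.8))
})

test_that("recontoured volumes correlate positively with original volumes", {
  vols <- t(vapply(1:30, function(s) {
    set.seed(s)
    sp <- tiny_spec(seed = s,
                    tumor_radius_mm = stats::runif(3, 5, 9))
    ph <- make_phantom(sp)
    m2 <- make_recontour_pair(ph$volume, ph$mask, 1.5, seed = 1000 + s)
    c(v1 = roi_volume_mm3(ph$mask), v2 = roi_volume_mm3(m2))
  }, c(v1 = 0, v2 = 0)))
  expect_gt(cor(vols[, "v1"], vols[, "v2"], method = "spearman"), 0)
})

test_that("excessive boundary perturbation that empties the mask errors", {
  a <- array(FALSE, c(12, 12, 12)); a[6:7, 6:7, 6:7] <- TRUE
  vol <- voxel_volume(array(0, c(12, 12, 12)), 1)
  msk <- roi_mask(a, 1)
  expect_error(make_recontour_pair(vol, msk, 50, seed = 2),
               "emptied or displaced")
})

test_that("cohort generator: censor_rate 0 gives all events; determinism", {
  sp <- cohort_spec(n_patients = 50, censor_rate = 0, seed = 9)
  co <- simulate_cohort(sp, texture = rnorm(50))
  expect_true(all(co$event_os == 1) && all(co$event_dfs == 1))
  co2 <- simulate_cohort(sp, texture = co$texture)
  expect_identical(co$time_os, co2$time_os)
})

test_that("cohort generator hits the requested censoring fraction", {
  sp <- cohort_spec(n_patients = 2000, censor_rate = 0.3, seed = 21)
  co <- simulate_cohort(sp, texture = rep(0, 2000))
  expect_lt(abs(mean(1 - co$event_os) - 0.3), 0.05)
})

test_that("under the null, random patient halves rarely differ in survival", {
  rejections <- vapply(1:50, function(s) {
    sp <- cohort_spec(n_patients = 100, clinical_effects = c(sexM = 0),
                      radiomic_effect = 0, seed = 100 + s)
    co <- simulate_cohort(sp, texture = rep(0, 100))
    set.seed(s)
    grp <- sample(rep(1:2, 50))
    km_logrank(grp, co, "os")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(!rejections), 0.9)
})

test_that("oracle c-index of the true texture parameter rises with |effect|", {
  oracle_c <- function(effect) {
    mean(vapply(1:20, function(s) {
      set.seed(s)
      z <- rnorm(400)
      sp <- cohort_spec(n_patients = 400, clinical_effects = c(sexM = 0),
                        radiomic_effect = effect, seed = 5000 + s)
      co <- simulate_cohort(sp, texture = z)
      harrell_cindex(effect * z, co$time_os, co$event_os)
    }, 0))
  }
  cs <- c(oracle_c(0.35), oracle_c(0.7), oracle_c(1.4))
  expect_true(all(diff(cs) > 0))
})
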