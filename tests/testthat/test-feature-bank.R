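test_that("GLCM matches hand enumeration on a 2x2 slab", {
  # levels [[1,1],[1,2]], single horizontal offset: ordered pairs (1,1),(1,2);
  # symmetrized and normalized -> P(1,1)=0.5, P(1,2)=P(2,1)=0.25
  d <- disc_from_levels(matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE), 2)
  g <- glcm_compute(d, offsets = list(c(0, 1, 0)))
  expect_equal(g$matrix, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
})

test_that("GLCM of a constant ROI is a point mass; single voxel errors", {
  d <- disc_from_levels(matrix(1L, 3, 3), 1)
  g <- glcm_compute(d)
  expect_equal(g$matrix, matrix(1, 1, 1))
  d1 <- disc_from_levels(matrix(1L, 1, 1), 1)
  expect_error(glcm_compute(d1), "degenerate ROI for GLCM")
})

test_that("GLCM is symmetric and sums to one on random phantoms", {
  for (s in 1:5) {
    ph <- make_phantom(tiny_spec(seed = s))
    d <- discretize(ph$volume, ph$mask, 32)
    g <- glcm_compute(d)
    expect_equal(sum(g$matrix), 1, tolerance = 1e-12)
    expect_equal(g$matrix, t(g$matrix), tolerance = 1e-12)
  }
})

test_that("GLRLM matches hand enumeration on a 1x5 row", {
  d <- disc_from_levels(array(c(1, 1, 2, 2, 2), c(5, 1, 1)), 2)
  g <- glrlm_compute(d, c(1, 0, 0))
  expect_identical(g$n_runs, 2L + 0L)
  expect_equal(g$matrix[1, 2], 1)  # one run of level 1, length 2
  expect_equal(g$matrix[2, 3], 1)  # one run of level 2, length 3
  expect_equal(sum(g$matrix), 2)
  expect_equal(feature_rp(g), 0.4)
  expect_equal(feature_gln_rl(g), 1)
})

test_that("constant and checkerboard slabs give the extreme run percentages", {
  d_const <- disc_from_levels(matrix(1L, 4, 4), 1)
  g <- glrlm_compute(d_const, c(1, 0, 0))
  expect_equal(feature_rp(g), 0.25)  # 4 runs of length 4 over 16 voxels
  board <- outer(1:8, 1:8, function(i, j) ((i + j) %% 2) + 1L)
  g2 <- glrlm_compute(disc_from_levels(board, 2), c(1, 0, 0))
  expect_equal(feature_rp(g2), 1)
  expect_true(all(g2$matrix[, -1] == 0))
})

test_that("GLN equals n_runs when one level holds all runs, and is minimized
           by an even spread (brute force over 6 runs, 3 levels)", {
  d1 <- disc_from_levels(matrix(1L, 2, 3), 1)
  g1 <- glrlm_compute(d1, c(1, 0, 0))
  expect_equal(feature_gln_rl(g1), g1$n_runs)
  # brute force: distribute 6 runs over 3 levels; GLN = sum(n_i^2)/6
  parts <- expand.grid(a = 0:6, b = 0:6, c = 0:6)
  parts <- parts[rowSums(parts) == 6, ]
  gln <- (parts$a^2 + parts$b^2 + parts$c^2) / 6
  expect_equal(unname(unlist(parts[which.min(gln), ])), c(2, 2, 2))
})

test_that("run-length conservation holds on 100 random phantoms, all directions", {
  for (s in 1:100) {
    set.seed(s)
    a <- array(sample(1:4, 8^3, TRUE), c(8, 8, 8))
    m <- array(stats::runif(8^3) > 0.4, c(8, 8, 8))
    if (!any(m)) next
    a[!m] <- NA
    d <- disc_from_levels(a, 4)
    for (o in offsets_3d()) {
      g <- glrlm_compute(d, o)
      expect_equal(sum(g$matrix %*% seq_len(ncol(g$matrix))), sum(m))
    }
  }
})

test_that("first-order features: degenerate and closed-form cases", {
  vol <- voxel_volume(array(7, c(3, 3, 3)), 1)
  msk <- roi_mask(array(TRUE, c(3, 3, 3)), 1)
  f <- first_order_features(vol, msk)
  expect_equal(unname(f[c("FO_variance", "FO_entropy", "FO_skewness")]),
               c(0, 0, 0))
  expect_equal(unname(f["FO_uniformity"]), 1)
  # 50/50 two-level ROI: entropy 1 bit, uniformity 0.5
  a <- array(rep(c(0, 10), each = 50), c(100, 1, 1))
  f2 <- first_order_features(voxel_volume(a, 1),
                             roi_mask(array(TRUE, c(100, 1, 1)), 1))
  expect_equal(unname(f2["FO_entropy"]), 1)
  expect_equal(unname(f2["FO_uniformity"]), 0.5)
  expect_equal(unname(f2["FO_mean"]), 5)
})

test_that("skewness of a symmetric texture field is centered on zero", {
  sk <- vapply(1:50, function(s) {
    ph <- make_phantom(tiny_spec(seed = s))
    unname(first_order_features(ph$volume, ph$mask)["FO_skewness"])
  }, 0)
  expect_lt(abs(mean(sk)), 3 * stats::sd(sk) / sqrt(50) + 0.05)
})

test_that("shape features: single voxel volume, sphere accuracy, intensity
           invariance", {
  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  f <- shape_features(roi_mask(a, 1))
  expect_equal(unname(f["SHAPE_volume"]), 1)
  # voxelized ball, r = 12 voxels: area within 2% of 4 pi r^2,
  # sphericity ~ 1 (may exceed 1 marginally: voxel counting overestimates
  # the ball volume while the coarea estimate of area is slightly low)
  r <- 12
  m <- roi_mask(ctradiomics:::ellipsoid_mask(c(40, 40, 40), c(1, 1, 1),
                                             rep(r, 3)), 1)
  fs <- shape_features(m)
  expect_lt(abs(fs[["SHAPE_surface_area"]] - 4 * pi * r^2) / (4 * pi * r^2),
            0.02)
  expect_gt(fs[["SHAPE_sphericity"]], 0.9)
  expect_lt(fs[["SHAPE_sphericity"]], 1.03)
  expect_lt(abs(fs[["SHAPE_max_diameter_3d"]] - 2 * r), 2)
})

test_that("wavelet sub-bands: constant input, Parseval, mask downsampling", {
  cvol <- voxel_volume(array(3, c(8, 8, 2)), 1)
  w <- wavelet_channels(cvol)
  expect_true(all(w$LH$data == 0) && all(w$HL$data == 0) &&
                all(w$HH$data == 0))
  expect_true(all(abs(w$LL$data - 3 * 2) < 1e-12))  # sqrt(2)^2 gain
  set.seed(3)
  rvol <- voxel_volume(array(rnorm(16 * 16 * 3), c(16, 16, 3)), 1)
  wr <- wavelet_channels(rvol)
  expect_equal(sum(vapply(wr, function(b) sum(b$data^2), 0)),
               sum(rvol$data^2), tolerance = 1e-10)
  m <- array(FALSE, c(8, 8, 2)); m[3:6, 3:6, ] <- TRUE
  dm <- downsample_mask(roi_mask(m, 1))
  expect_identical(dim(dm$data), c(4L, 4L, 2L))
  expect_equal(sum(dm$data), 2 * 2 * 2)  # in-plane blocks 2:3 each axis
  expect_error(wavelet_channels(voxel_volume(array(0, c(1, 5, 5)), 1)),
               "at least 2x2")
})

test_that("extraction honors the manifest: order, determinism, 271 names", {
  ph <- make_phantom(tiny_spec(seed = 8))
  man <- default_manifest()
  fv <- extract_features(ph$volume, ph$mask, man)
  expect_length(fv, 271)
  expect_identical(names(fv), man$name)
  expect_true(all(is.finite(fv)))
  fv2 <- extract_features(ph$volume, ph$mask, man)
  expect_identical(fv, fv2)
  perm <- man[rev(seq_len(nrow(man))), ]
  fvp <- extract_features(ph$volume, ph$mask, perm)
  expect_identical(unname(c(fvp)), unname(rev(c(fv))))
  expect_identical(names(fvp), rev(names(fv)))
})

test_that("features ignore mask-exterior intensities", {
  ph <- make_phantom(tiny_spec(seed = 9))
  man <- default_manifest()
  man <- man[man$channel == "original", ]  # wavelet support crosses the
                                           # boundary by construction
  fv1 <- extract_features(ph$volume, ph$mask, man)
  v2 <- ph$volume
  v2$data[!ph$mask$data] <- v2$data[!ph$mask$data] + 500
  fv2 <- extract_features(v2, ph$mask, man)
  expect_equal(fv1, fv2, tolerance = 1e-12)
})

test_that("direction-aggregated texture features are invariant to 90-degree
           in-plane rotation", {
  ph <- make_phantom(tiny_spec(seed = 10))
  rot <- function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
  v2 <- voxel_volume(rot(ph$volume$data), 1)
  m2 <- roi_mask(rot(ph$mask$data), 1)
  d1 <- discretize(ph$volume, ph$mask, 16)
  d2 <- discretize(v2, m2, 16)
  expect_equal(glcm_features(glcm_compute(d1)),
               glcm_features(glcm_compute(d2)), tolerance = 1e-10)
  expect_equal(ctradiomics:::glrlm_features_mean(d1, offsets_3d()),
               ctradiomics:::glrlm_features_mean(d2, offsets_3d()),
               tolerance = 1e-10)
})

test_that("run percentage decreases as texture gets smoother", {
  mean_rp <- function(cl) {
    mean(vapply(1:6, function(s) {
      ph <- make_phantom(tiny_spec(seed = s, texture_corr_length_mm = cl,
                                   noise_sd = 0))
      d <- discretize(ph$volume, ph$mask, 32)
      mean(vapply(offsets_3d(),
                  function(o) feature_rp(glrlm_compute(d, o)), 0))
    }, 0))
  }
  rps <- c(mean_rp(1), mean_rp(3), mean_rp(8))
  expect_true(all(diff(rps) < 0))
})
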