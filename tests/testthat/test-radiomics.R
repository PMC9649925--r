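test_that("the wavelet decomposition returns 8 same-shape sub-bands", {
  v <- random_volume(c(10L, 8L, 6L), seed = 2)
  sb <- wavelet_subbands(v)
  expect_length(sb, 8L)
  expect_identical(names(sb), subband_names())
  for (b in sb) expect_identical(dim(b), dim(v))
  expect_error(wavelet_subbands(array(0, c(5, 1, 5))), "dimension")
})

test_that("all detail sub-bands of a constant volume vanish", {
  sb <- wavelet_subbands(array(3.2, c(6, 6, 4)))
  for (b in setdiff(subband_names(), "LLL")) {
    expect_equal(max(abs(sb[[b]])), 0)
  }
  # the low-pass band carries the (rescaled) constant
  expect_equal(sb$LLL[2, 2, 2], 3.2 * 2^1.5, tolerance = 1e-12)
})

test_that("intensity features match hand-computed values", {
  f <- intensity_features(c(1, 2, 3, 4))
  expect_length(f, 18L)
  expect_identical(names(f), strokerad:::INTENSITY_NAMES)
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["range"]), 3)
  expect_equal(unname(f["energy"]), 30)       # 1 + 4 + 9 + 16
  expect_equal(unname(f["rms"]), sqrt(30 / 4))
  expect_equal(unname(f["minimum"]), 1)
  expect_equal(unname(f["maximum"]), 4)
})

test_that("constant regions use the documented degenerate conventions", {
  f <- intensity_features(rep(7, 25))
  expect_equal(unname(f["mean"]), 7)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["uniformity"]), 1)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 0)
  expect_error(intensity_features(numeric(0)), "empty")
})

test_that("texture features of a constant lesion follow the conventions", {
  v <- array(2.5, c(8, 8, 6))
  m <- make_block_mask(c(8L, 8L, 6L), c(2L, 2L, 2L), c(6L, 6L, 5L))
  tf <- texture_features(v, m)
  expect_length(tf, 39L)
  expect_equal(unname(tf["glcm_contrast"]), 0)
  expect_equal(unname(tf["glcm_joint_entropy"]), 0)
  expect_equal(unname(tf["glcm_inverse_difference"]), 1)
  expect_equal(unname(tf["glcm_inverse_difference_moment"]), 1)
  expect_equal(unname(tf["glcm_correlation"]), 1)
  expect_equal(unname(tf["glcm_maximum_probability"]), 1)
})

test_that("a 2-level checkerboard has co-occurrence contrast exactly 1", {
  # 1-voxel-thick slab; every horizontal neighbour pair differs by 1 level
  cb <- array(0, c(8, 8, 1))
  cb[] <- (row(cb[, , 1]) + col(cb[, , 1])) %% 2
  m <- array(1L, c(8, 8, 1))
  tf <- texture_features(cb, m, quantization_spec(2),
                         offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(tf["glcm_contrast"]), 1)
  # run-length view: no horizontal run exceeds length 1
  expect_equal(unname(tf["glrlm_sre"]), 1)
  expect_equal(unname(tf["glrlm_rp"]), 1)
})

test_that("run-length features match a hand-enumerated line", {
  # single line 1,1,2,2,2: runs (level 1, len 2) and (level 2, len 3)
  v <- array(0, c(5, 1, 1)); v[, 1, 1] <- c(1, 1, 2, 2, 2)
  m <- array(1L, c(5, 1, 1))
  tf <- texture_features(v, m, quantization_spec(2),
                         offsets = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(tf["glrlm_sre"]), (1 / 4 + 1 / 9) / 2)
  expect_equal(unname(tf["glrlm_lre"]), (4 + 9) / 2)
  expect_equal(unname(tf["glrlm_rp"]), 2 / 5)
  expect_equal(unname(tf["glrlm_run_entropy"]), 1)   # two equiprobable runs
})

test_that("degenerate masks are handled: empty errors, single voxel works", {
  v <- random_volume(c(8L, 8L, 6L), seed = 3)
  expect_error(texture_features(v, array(0L, c(8, 8, 6))), "empty mask")
  m1 <- array(0L, c(8, 8, 6)); m1[4, 4, 3] <- 1L
  tf <- texture_features(v, m1)
  expect_length(tf, 39L)
  expect_true(all(is.finite(tf)))
  expect_equal(unname(tf["glcm_contrast"]), 0)   # single-cell convention
})

test_that("the extractor emits the full 513-feature manifest", {
  mf <- feature_manifest()
  expect_equal(nrow(mf), 513L)
  expect_equal(sum(mf$family == "intensity"), 18L * 9L)
  expect_equal(sum(mf$family == "texture"), 39L * 9L)
  expect_equal(length(unique(mf$name)), 513L)
  expect_equal(length(unique(mf$domain)), 9L)

  v <- random_volume(); m <- make_block_mask()
  f <- extract_features(v, m)
  expect_length(f, 513L)
  expect_identical(names(f), mf$name)
  expect_true(all(is.finite(f)))
  # determinism
  expect_identical(f, extract_features(v, m))
})

test_that("masks below 50 voxels raise the exclusion error", {
  v <- random_volume()
  m <- array(0L, c(16, 16, 10)); m[1:7, 1:7, 1] <- 1L  # 49 voxels
  expect_error(extract_features(v, m), "excluded")
  m[8, 1, 1] <- 1L                                      # 50 voxels
  expect_silent(extract_features(v, m))
})

test_that("features are invariant to joint whole-voxel translations", {
  v <- random_volume(c(18L, 18L, 12L), seed = 8)
  m <- make_block_mask(c(18L, 18L, 12L), c(4L, 4L, 4L), c(9L, 9L, 8L))
  f1 <- extract_features(v, m)
  # shift volume and mask by (2, 1, 1); lesion stays off the borders
  shift <- function(a, s) {
    out <- array(0, dim(a))
    d <- dim(a)
    out[(1 + s[1]):d[1], (1 + s[2]):d[2], (1 + s[3]):d[3]] <-
      a[1:(d[1] - s[1]), 1:(d[2] - s[2]), 1:(d[3] - s[3])]
    out
  }
  # background voxels also move, so re-generate: translate both arrays
  v2 <- shift(v, c(2, 1, 1)); m2 <- shift(m, c(2, 1, 1))
  f2 <- extract_features(v2, m2)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("adding a constant shifts location features and spares texture", {
  v <- random_volume(c(16L, 16L, 10L), seed = 9)
  m <- make_block_mask()
  f1 <- extract_features(v, m)
  f2 <- extract_features(v + 10, m)
  for (nm in c("image_intensity_mean", "image_intensity_median",
               "image_intensity_p10", "image_intensity_p90")) {
    expect_equal(unname(f2[nm] - f1[nm]), 10, tolerance = 1e-9)
  }
  expect_equal(f2["image_intensity_variance"], f1["image_intensity_variance"],
               tolerance = 1e-9)
  # min-max quantization makes texture features shift-invariant
  tex <- grep("image_gl", names(f1), value = TRUE)
  expect_equal(f2[tex], f1[tex], tolerance = 1e-9)
})

test_that("co-occurrence correlation tracks the texture correlation length", {
  corr_at <- function(scale, seed) {
    sp <- synthesize_lesion_pair(lesion_volume = 250, texture_scale = scale,
                                 texture_amplitude = 0.3, noise_sd = 0,
                                 n_blobs = 1, seed = seed)
    texture_features(sp$adc, sp$mask)["glcm_correlation"]
  }
  smooth_wins <- sum(vapply(1:6, function(s) {
    corr_at(2.0, 600 + s) > corr_at(0.3, 600 + s)
  }, logical(1)))
  expect_gte(smooth_wins, 5L)
})
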