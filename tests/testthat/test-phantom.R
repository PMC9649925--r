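test_that("lesion volume calibration lands within 10% of the request", {
  vols <- vapply(1:20, function(s) {
    sp <- synthesize_lesion_pair(lesion_volume = 500,
                                 volume_shape = c(32L, 32L, 24L), seed = s)
    sum(sp$mask)
  }, numeric(1))
  expect_true(all(abs(vols - 500) / 500 <= 0.10))
})

test_that("degenerate texture and noise give a constant lesion interior", {
  sp <- synthesize_lesion_pair(texture_amplitude = 0, noise_sd = 0, seed = 4)
  vals <- sp$dwi[sp$mask > 0]
  expect_equal(var(vals), 0)
  # downstream first-order variance is 0 too
  expect_equal(unname(intensity_features(vals)["variance"]), 0)
})

test_that("lesion synthesis is deterministic given the seed", {
  a <- synthesize_lesion_pair(seed = 99)
  b <- synthesize_lesion_pair(seed = 99)
  expect_identical(a, b)
  c <- synthesize_lesion_pair(seed = 100)
  expect_false(identical(a$dwi, c$dwi))
})

test_that("lesion contrast signs hold against the surrounding parenchyma", {
  for (s in 1:8) {
    sp <- draw_phantom_subject(400 + s)
    les <- sp$mask > 0
    paren <- sp$brain & !les
    expect_gt(mean(sp$dwi[les]), mean(sp$dwi[paren]))
    expect_lt(mean(sp$adc[les]), mean(sp$adc[paren]))
  }
})

test_that("oversized lesions are rejected with a geometry error", {
  expect_error(synthesize_lesion_pair(volume_shape = c(12L, 12L, 8L),
                                      lesion_volume = 2000, seed = 1),
               "does not fit")
})

test_that("zero planted effects give every subject the target prevalence", {
  cfg <- phantom_config(n_subjects = 50, effect_weights = c(),
                        clinical_effects = c(), seed = 3)
  feats <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  al <- assign_labels(feats, NULL, cfg, seed = 7)
  expect_equal(al$probabilities, rep(0.085, 50))
})

test_that("unknown effect names raise configuration errors", {
  cfg <- phantom_config(effect_weights = c(not_a_feature = 1))
  feats <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(assign_labels(feats, NULL, cfg), "unknown feature")
  cfg2 <- phantom_config(effect_weights = c(), clinical_effects = c(shoe_size = 1))
  expect_error(assign_labels(feats, data.frame(age = rnorm(10)), cfg2),
               "unknown covariate")
})

test_that("label prevalence calibrates to 8.5% under binomial draws", {
  # law-of-large-numbers check at n = 10,000 with planted effects active
  n <- 10000L
  cfg <- phantom_config(n_subjects = n, exact_count = FALSE,
                        clinical_effects = c(), seed = 5)
  feats <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(NULL, names(cfg$effect_weights)))
  al <- assign_labels(feats, NULL, cfg, seed = 11)
  expect_equal(mean(al$probabilities), 0.085, tolerance = 1e-6)
  mc_sd <- sqrt(0.085 * 0.915 / n)
  expect_lt(abs(mean(al$labels) - 0.085), 3 * mc_sd)
})

test_that("a strongly weighted feature raises recurrence in its top decile", {
  n <- 10000L
  cfg <- phantom_config(n_subjects = n, exact_count = FALSE,
                        effect_weights = c(x = 2.0), clinical_effects = c(),
                        seed = 6)
  feats <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  al <- assign_labels(feats, NULL, cfg, seed = 12)
  qs <- quantile(feats[, 1], c(0.1, 0.9))
  top <- mean(al$labels[feats[, 1] >= qs[2]])
  bottom <- mean(al$labels[feats[, 1] <= qs[1]])
  expect_gt(top, bottom)
})

test_that("exact-count cohorts hit the printed positive count", {
  # 1,003 subjects at 8.5% prevalence -> 85 recurrences; checked on labels
  # assigned to a feature-free cohort to keep the test fast
  n <- 1003L
  cfg <- phantom_config(n_subjects = n, effect_weights = c(), seed = 8)
  al <- assign_labels(NULL, sample_clinical(n), cfg, seed = 2)
  expect_equal(sum(al$labels), 85L)
})

test_that("small cohorts generate valid files and identical CSVs per seed", {
  cfg <- phantom_config(n_subjects = 2, seed = 7,
                        effect_weights = c(image_intensity_mean = -0.9))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co1 <- generate_cohort(cfg, out_dir = d1)
  co2 <- generate_cohort(cfg, out_dir = d2)
  expect_equal(nrow(co1$clinical), 2L)
  expect_true(file.exists(file.path(d1, "sub-0001_dwi.nii.gz")))
  expect_true(file.exists(file.path(d1, "sub-0002_mask.nii.gz")))
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  # round-trip: the written mask equals the in-memory mask
  co3 <- generate_cohort(cfg, keep_volumes = TRUE)
  m <- RNifti::readNifti(file.path(d1, "sub-0001_mask.nii.gz"))
  expect_equal(sum(m), sum(co3$subjects[[1]]$mask))
})

test_that("a single-subject cohort is a valid boundary case", {
  cfg <- phantom_config(n_subjects = 1, effect_weights = c(), seed = 9)
  co <- generate_cohort(cfg, extract = FALSE)
  expect_equal(nrow(co$clinical), 1L)
  expect_true(co$clinical$recurrence %in% c(0L, 1L))
})

test_that("clinical covariates mimic the study margins", {
  set.seed(21)
  cl <- sample_clinical(4000)
  expect_equal(mean(cl$age), 65.9, tolerance = 0.02)
  expect_equal(sd(cl$age), 12.44, tolerance = 0.05)
  expect_equal(mean(cl$sex == "male"), 682 / 1003, tolerance = 0.05)
  expect_equal(mean(cl$statins_after_discharge), 634 / 1003, tolerance = 0.05)
  toast <- table(cl$toast_subtype) / nrow(cl)
  expect_equal(unname(toast["LAA"]), 544 / 1003, tolerance = 0.05)
})
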