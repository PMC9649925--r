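test_that("the under-sampling split reproduces the study arithmetic", {
  set.seed(71)
  labels <- sample(rep(c(1L, 0L), times = c(85, 918)))
  sp <- build_split(labels, 57, 100, seed = 3)
  expect_length(sp$train, 157L)
  expect_length(sp$test, 846L)
  expect_equal(sp$counts$test_pos, 28L)
  expect_equal(sp$counts$test_neg, 818L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
})

test_that("splits are deterministic in the seed and honest about shortfalls", {
  labels <- rep(c(1L, 0L), times = c(10, 30))
  a <- build_split(labels, 5, 10, seed = 9)
  b <- build_split(labels, 5, 10, seed = 9)
  expect_identical(a, b)
  c <- build_split(labels, 5, 10, seed = 10)
  expect_false(identical(a$train, c$train))
  expect_equal(c(length(c$train), length(c$test)), c(15L, 25L))
  # request 0/0 -> empty train, everything in test
  z <- build_split(labels, 0, 0, seed = 1)
  expect_length(z$train, 0L)
  expect_length(z$test, 40L)
  expect_error(build_split(labels, 11, 10, seed = 1), "insufficient positives")
  expect_error(build_split(labels, 5, 31, seed = 1), "insufficient negatives")
})

test_that("weighted cross-entropy matches its closed forms", {
  # coin-flip predictions at unit weights cost ln 2
  expect_equal(weighted_cross_entropy(rep(0.5, 8), rep(c(0, 1), 4)), log(2))
  # near-perfect predictions cost ~0
  expect_lt(weighted_cross_entropy(c(1e-9, 1 - 1e-9), c(0, 1)), 1e-5)
  # doubling the positive weight doubles the positive sample's contribution
  p <- c(0.3, 0.8); y <- c(0, 1)
  base <- weighted_cross_entropy(p, y, c(1, 1))
  up <- weighted_cross_entropy(p, y, c(1, 2))
  expect_equal(up - base, -log(0.8) / 2, tolerance = 1e-12)
  expect_error(weighted_cross_entropy(p, y, c(0, 1)), "> 0")
})

test_that("the GRU learns a separable planted signal", {
  set.seed(72)
  n <- 150L
  X <- matrix(rnorm(n * 513), n, 513)
  colnames(X) <- feature_manifest()$name
  planted <- c(5L, 70L, 130L)
  lp <- 1.6 * rowSums(X[, planted])
  y <- as.integer(lp + rnorm(n, 0, 0.5) > 0)
  tr <- 1:100; te <- 101:150
  fit <- train_rnn(X[tr, ], y[tr],
                   rnn_config(epochs = 60, learning_rate = 1e-3,
                              validation_fraction = 0, seed = 5),
                   selected = planted)
  expect_gt(roc_auc(predict(fit, X[te, ]), y[te])$auc, 0.9)
  # training loss decreases
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("GRU training and inference are deterministic and layout-checked", {
  set.seed(73)
  X <- matrix(rnorm(60 * 513), 60, 513)
  y <- rep(c(0L, 1L), 30)
  cfg <- rnn_config(epochs = 4, learning_rate = 1e-3, seed = 11)
  f1 <- train_rnn(X, y, cfg)
  f2 <- train_rnn(X, y, cfg)
  expect_equal(f1$params, f2$params, tolerance = 1e-14)
  expect_equal(f1$history$loss, f2$history$loss)
  p1 <- predict(f1, X)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict(f1, X))
  # permuting subjects permutes predictions identically
  perm <- sample(60)
  expect_equal(predict(f1, X[perm, ]), p1[perm], tolerance = 1e-12)
  expect_error(train_rnn(X[, 1:100], y, cfg), "layout mismatch")
})

test_that("class weighting beats a constant predictor on imbalanced data", {
  # with inverse-frequency weights, predicting the majority class everywhere
  # is costlier than an informative rule: the weighting has teeth
  y <- rep(c(0L, 1L), times = c(90, 10))
  w <- c(1 / 0.9, 1 / 0.1) / mean(c(1 / 0.9, 1 / 0.1))
  const <- weighted_cross_entropy(rep(0.01, 100), y, w)
  informative <- weighted_cross_entropy(ifelse(y == 1, 0.7, 0.2), y, w)
  expect_gt(const, informative)
  # while at UNIT weights the constant majority predictor is cheap
  expect_lt(weighted_cross_entropy(rep(0.01, 100), y),
            weighted_cross_entropy(rep(0.5, 100), y))
})

test_that("the clinical logistic recovers a 2x2 odds ratio", {
  # single binary covariate with counts: exposed 40 (12 events),
  # unexposed 60 (6 events) -> OR = (12/28) / (6/54)
  x <- rep(c(1, 0), times = c(40, 60))
  y <- c(rep(c(1, 0), times = c(12, 28)), rep(c(1, 0), times = c(6, 54)))
  fit <- train_clinical_logistic(data.frame(exposure = x), y)
  or_emp <- (12 / 28) / (6 / 54)
  expect_equal(exp(unname(fit$coefficients["exposure"])), or_emp,
               tolerance = 1e-3)
})

test_that("zero-signal covariates yield chance-level held-out AUC", {
  set.seed(74)
  n <- 600L
  cl <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4), c = rnorm(n))
  y <- rbinom(n, 1, 0.2)
  fit <- train_clinical_logistic(cl[1:300, ], y[1:300])
  auc <- roc_auc(predict(fit, cl[301:n, ]), y[301:n])$auc
  expect_lt(abs(auc - 0.5), 0.12)
})

test_that("constant columns do not perturb logistic predictions", {
  set.seed(75)
  cl <- data.frame(x = rnorm(80))
  y <- rbinom(80, 1, plogis(cl$x))
  f1 <- train_clinical_logistic(cl, y)
  f2 <- train_clinical_logistic(cbind(cl, k = 1), y)
  expect_equal(predict(f1, cl), predict(f2, cbind(cl, k = 1)), tolerance = 1e-6)
})

test_that("factor covariates are one-hot encoded with stable levels", {
  set.seed(76)
  cl <- data.frame(subtype = sample(c("LAA", "SAO", "CE"), 90, replace = TRUE),
                   stringsAsFactors = FALSE)
  y <- rbinom(90, 1, ifelse(cl$subtype == "LAA", 0.5, 0.2))
  fit <- train_clinical_logistic(cl, y)
  # prediction on a subset with a missing level still works
  sub <- cl[cl$subtype != "CE", , drop = FALSE]
  expect_length(predict(fit, sub), nrow(sub))
})
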