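test_that("AUC matches the pair-counting definition on worked examples", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  # ties count one half
  expect_equal(roc_auc(c(1, 1), c(0, 1))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC respects label complement and monotone-transform symmetries", {
  set.seed(51)
  for (i in 1:5) {
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, 1 - y)$auc, 1 - roc_auc(s, y)$auc)
    expect_equal(roc_auc(exp(2 * s) + 5, y)$auc, roc_auc(s, y)$auc)
  }
})

test_that("AUC and DeLong CI agree with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  y <- rbinom(120, 1, 0.3)
  s <- rnorm(120) + y
  ours <- roc_auc(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- pROC::ci.auc(ref, method = "delong")
  # same DeLong variance; interval transforms differ slightly (logit vs raw)
  expect_equal(ours$ci_low, as.numeric(ci[1]), tolerance = 0.02)
  expect_equal(ours$ci_high, as.numeric(ci[3]), tolerance = 0.02)
})

test_that("the DeLong variance is coherent with Hanley-McNeil on clean data", {
  set.seed(53)
  y <- rep(c(0, 1), each = 150)
  s <- rnorm(300) + y
  r <- roc_auc(s, y)
  a <- r$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  hm <- sqrt((a * (1 - a) + 149 * (q1 - a^2) + 149 * (q2 - a^2)) / (150 * 150))
  expect_lt(abs(r$se - hm), 0.2 * hm)
})

test_that("identical scores give a DeLong p of 1 with a warning", {
  set.seed(54)
  y <- rbinom(40, 1, 0.5)
  s <- rnorm(40)
  expect_warning(res <- delong_test(s, s, y), "zero estimated variance")
  expect_equal(res$p_value, 1)
  expect_equal(res$difference, 0)
})

test_that("DeLong p agrees with paired pROC and with a bootstrap oracle", {
  skip_if_not_installed("pROC")
  set.seed(55)
  y <- rbinom(60, 1, 0.4)
  a <- rnorm(60) + 0.8 * y
  b <- rnorm(60) + 0.3 * y
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("stronger separation in one model drives the DeLong p down", {
  set.seed(56)
  pvals <- vapply(c(0.3, 0.9, 1.6), function(delta) {
    mean(vapply(1:20, function(i) {
      y <- rep(c(0, 1), times = c(40, 20))
      a <- rnorm(60) + delta * y
      b <- rnorm(60)
      delong_test(a, b, y)$p_value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(pvals) < 0))
})

test_that("confusion metrics match hand counts and threshold extremes", {
  # scores (0.2, 0.6, 0.7), labels (0, 0, 1): at a 0.5 cut the 0.6 negative
  # is a false positive -> accuracy 2/3, sensitivity 1, specificity 1/2
  cm <- confusion_metrics(c(0.2, 0.6, 0.7), c(0, 0, 1), 0.5)
  expect_equal(cm$accuracy, 2 / 3, tolerance = 1e-12)
  expect_equal(cm$sensitivity, 1.0)
  expect_equal(cm$specificity, 0.5)
  # a cut above 0.6 classifies only the true positive as positive
  cm2 <- confusion_metrics(c(0.2, 0.6, 0.7), c(0, 0, 1), 0.65)
  expect_equal(cm2$accuracy, 1.0)
  s <- runif(30); y <- rep(c(0, 1), 15)
  expect_equal(confusion_metrics(s, y, min(s) - 1)$sensitivity, 1.0)
  expect_equal(confusion_metrics(s, y, max(s) + 1)$specificity, 1.0)
})

test_that("net-benefit curves follow their closed forms", {
  set.seed(57)
  n <- 2000L
  y <- rbinom(n, 1, 0.085)
  if (sum(y) == 0) y[1] <- 1L
  # treat-none is identically 0; treat-all crosses 0 at t = prevalence
  dc <- decision_curve(runif(n), y, grid = seq(0.01, 0.5, by = 0.01))
  expect_true(all(dc$nb_treat_none == 0))
  prev <- mean(y)
  t_at <- dc$threshold[which.min(abs(dc$threshold - prev))]
  nb_at <- prev - (1 - prev) * t_at / (1 - t_at)
  expect_equal(dc$nb_treat_all[dc$threshold == t_at], nb_at, tolerance = 1e-12)
  # a perfect classifier attains NB(t) = prevalence everywhere
  dcp <- decision_curve(y, y, grid = seq(0.05, 0.5, by = 0.05))
  expect_equal(dcp$nb_model, rep(prev, nrow(dcp)), tolerance = 1e-12)
  # no model exceeds the prevalence ceiling
  expect_true(all(dc$nb_model <= prev + 1e-12))
  expect_error(decision_curve(runif(n), y, grid = c(0.5, 1)), "inside")
})

test_that("the Youden threshold maximises sensitivity + specificity - 1", {
  set.seed(58)
  s <- c(rnorm(50, 0), rnorm(25, 1.5))
  y <- rep(c(0, 1), times = c(50, 25))
  th <- youden_threshold(s, y)
  j_at <- function(t) {
    cm <- confusion_metrics(s, y, t)
    cm$sensitivity + cm$specificity - 1
  }
  expect_true(all(j_at(th) >= vapply(sort(unique(s)), j_at, numeric(1)) - 1e-12))
})
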