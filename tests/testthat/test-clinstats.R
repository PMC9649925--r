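test_that("the pooled t-test reproduces the printed age comparison", {
  # group summaries as printed in the cohort table
  res <- t_test_pooled(918, 65.55, 12.35, 85, 69.74, 12.79)
  expect_equal(round(res$p_value, 3), 0.003)
  expect_equal(res$df, 1001)
  # Welch variant on the same inputs
  resw <- t_test_pooled(918, 65.55, 12.35, 85, 69.74, 12.79, welch = TRUE)
  expect_equal(round(resw$p_value, 3), 0.005)
  expect_equal(resw$df, 99.06, tolerance = 0.01)
})

test_that("identical summaries give t = 0, p = 1", {
  res <- t_test_pooled(30, 5, 2, 40, 5, 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res0 <- t_test_pooled(10, 3, 0, 10, 3, 0)
  expect_equal(res0$p_value, 1)
})

test_that("summary-based and raw-data t-tests coincide", {
  set.seed(61)
  x <- rnorm(40, 10, 2); y <- rnorm(25, 11, 3)
  a <- t_test_raw(x, y)
  b <- t_test_pooled(40, mean(x), sd(x), 25, mean(y), sd(y))
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  # and both agree with the reference implementation
  expect_equal(a$p_value, t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(t_test_raw(x, y, welch = TRUE)$p_value, t.test(x, y)$p.value,
               tolerance = 1e-12)
})

test_that("Mann-Whitney handles the documented extremes", {
  res <- mann_whitney(c(10, 11, 12), c(1, 2, 3, 4))
  expect_equal(res$U, 12)                     # n1 * n2, full separation
  expect_lt(res$p_value, 0.06)                # minimal exact p = 2/C(7,3)
  expect_equal(res$method, "exact")
  # identical multisets -> p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("the exact Mann-Whitney p equals brute-force enumeration", {
  brute <- function(x, y) {
    # two-sided p over all C(n1+n2, n1) group assignments
    all <- c(x, y)
    n1 <- length(x)
    u_of <- function(idx) {
      r <- rank(all)
      sum(r[idx]) - n1 * (n1 + 1) / 2
    }
    u_obs <- u_of(seq_len(n1))
    mu <- n1 * (length(all) - n1) / 2
    us <- utils::combn(length(all), n1, u_of)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  set.seed(62)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    ours <- mann_whitney(x, y)
    expect_equal(ours$method, "exact")
    expect_equal(ours$p_value, brute(x, y), tolerance = 1e-9)
  }
})

test_that("chi-square reproduces the printed sex and statins p-values", {
  # counts from the cohort table: male 626/56, female 292/29
  sex <- chi_square(matrix(c(626, 292, 56, 29), 2), mode = "pearson")
  expect_equal(round(sex$p_value, 3), 0.662)
  # statins after discharge: no 350/19, yes 568/66
  st <- chi_square(matrix(c(350, 568, 19, 66), 2), mode = "pearson")
  expect_equal(round(st$p_value, 3), 0.004)
  # auto mode picks uncorrected Pearson here (all expected counts >= 5)
  expect_identical(chi_square(matrix(c(626, 292, 56, 29), 2))$mode_used, "pearson")
})

test_that("chi-square follows the closed 2x2 form and degenerate rules", {
  set.seed(63)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    res <- chi_square(tab, mode = "pearson")
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    N <- sum(tab)
    closed <- N * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$statistic, closed, tolerance = 1e-12)
  }
  uni <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(uni$statistic, 0)
  expect_equal(uni$p_value, 1)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "degenerate")
})

test_that("auto mode switches to Fisher below the expected-count rule", {
  tab <- matrix(c(2, 8, 9, 1), 2)       # small expected cells
  res <- chi_square(tab)
  expect_identical(res$mode_used, "fisher")
  expect_equal(res$p_value, fisher.test(tab)$p.value, tolerance = 1e-12)
  # Fisher p >= the point probability of the observed table
  expect_gte(res$p_value, dhyper(tab[1, 1], sum(tab[1, ]), sum(tab[2, ]),
                                 sum(tab[, 1])))
})

test_that("table one summarises a synthetic cohort with sensible tests", {
  set.seed(64)
  cl <- sample_clinical(300)
  # plant a clear age effect
  age_z <- (cl$age - mean(cl$age)) / sd(cl$age)
  rec <- rbinom(300, 1, plogis(-2.2 + 1.5 * age_z))
  cohort <- cbind(cl, recurrence = rec)
  tab <- table_one(cohort)
  expect_true(all(c("variable", "p_value", "p_formatted") %in% names(tab)))
  expect_equal(nrow(tab), length(setdiff(names(cohort), "recurrence")))
  age_row <- tab[tab$variable == "age", ]
  expect_identical(age_row$test, "t")
  expect_lt(age_row$p_value, 0.05)
  # score-like variables use the rank test
  expect_identical(tab[tab$variable == "nihss", "test"], "mann-whitney")

  # stratified layout mirrors the subtype table
  tab2 <- table_one(cohort, strata = "toast_subtype")
  expect_setequal(unique(tab2$stratum), unique(cl$toast_subtype))

  # a single-class grouping skips the tests but still summarises
  cohort0 <- cbind(cl, recurrence = 0L)
  tab0 <- table_one(cohort0)
  expect_true(all(is.na(tab0$p_value)))
  expect_true(all(grepl("skipped", tab0$test)))
})
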