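## Cohort comparison statistics: two-sample t-tests computable from printed
## summary statistics, Mann-Whitney U with an exact small-sample path,
## chi-square / Fisher contingency tests with the clinical-table convention
## for choosing between them, and a "table one" cohort report.

#' Two-sample t-test from group summaries
#'
#' Pooled-variance (Student) two-sample t-test computed from per-group
#' summary statistics (n, mean, SD), as printed in clinical tables, with
#' `df = n1 + n2 - 2`. Set `welch = TRUE` for the unequal-variance Welch
#' variant with Welch-Satterthwaite degrees of freedom. [t_test_raw()]
#' wraps the same formula for raw samples.
#'
#' @param n1,mean1,sd1 first group summary.
#' @param n2,mean2,sd2 second group summary.
#' @param welch use the Welch unequal-variance variant (default FALSE).
#' @return list with `statistic`, `df`, `p_value`, `mean_difference`.
#' @examples
#' t_test_pooled(918, 65.55, 12.35, 85, 69.74, 12.79)$p_value
#' @export
t_test_pooled <- function(n1, mean1, sd1, n2, mean2, sd2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  d <- mean1 - mean2
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    if (se2 == 0) return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1, mean_difference = d))
    stat <- d / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    if (sp2 == 0) {
      return(list(statistic = 0, df = df, p_value = if (d == 0) 1 else NA_real_,
                  mean_difference = d))
    }
    stat <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(statistic = stat, df = df, p_value = 2 * pt(-abs(stat), df),
       mean_difference = d)
}

#' @rdname t_test_pooled
#' @param x,y raw samples.
#' @export
t_test_raw <- function(x, y, welch = FALSE) {
  t_test_pooled(length(x), mean(x), sd(x), length(y), mean(y), sd(y), welch = welch)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with U counted by the midrank convention (ties contribute
#' 1/2). For tie-free samples with `n1 * n2 <= exact_limit` the two-sided
#' p-value comes from the exact null distribution of U; otherwise from the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit largest `n1 * n2` for the exact path (default 400).
#' @return list with `U` (for `x` vs `y`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_limit = 400L) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 * n2 <= exact_limit) {
    ## exact null distribution of U (stats::pwilcox enumerates it)
    p <- 2 * min(pwilcox(U, n1, n2), 1 - pwilcox(U - 1, n1, n2))
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * pnorm(-z)), method = "normal")
}

#' Contingency-table tests
#'
#' Pearson chi-square (with or without Yates continuity correction) and
#' Fisher's exact test for r x c count tables. The `"auto"` mode follows
#' the clinical-table convention: Pearson without correction when every
#' expected count is at least 5; otherwise Fisher's exact test for 2 x 2
#' tables (Pearson with a warning for larger ones).
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2.
#' @param mode `"auto"`, `"pearson"`, `"yates"` or `"fisher"`.
#' @return list with `statistic` (NA for Fisher), `df`, `p_value`,
#'   `mode_used`, `expected`.
#' @examples
#' chi_square(matrix(c(626, 292, 56, 29), 2))$p_value  # sex vs recurrence
#' @export
chi_square <- function(tab, mode = c("auto", "pearson", "yates", "fisher")) {
  mode <- match.arg(mode)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a marginal row/column total is zero")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (mode == "auto") {
    if (all(E >= 5)) {
      mode <- "pearson"
    } else if (all(dim(tab) == 2L)) {
      mode <- "fisher"
    } else {
      warning("expected counts < 5 in an r x c table; using Pearson chi-square")
      mode <- "pearson"
    }
  }
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  if (mode == "fisher") {
    p <- fisher.test(tab)$p.value
    return(list(statistic = NA_real_, df = df, p_value = p,
                mode_used = "fisher", expected = E))
  }
  if (mode == "yates") {
    if (!all(dim(tab) == 2L)) stop("Yates correction applies to 2 x 2 tables only")
    stat <- sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
  } else {
    stat <- sum((tab - E)^2 / E)
  }
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE),
       mode_used = mode, expected = E)
}

## variables treated as non-normal (median/IQR + Mann-Whitney) in table_one
TABLEONE_NONNORMAL <- c("nihss", "mrs90")

summarize_continuous <- function(x, g, var, nonnormal) {
  x0 <- x[g == 0L]; x1 <- x[g == 1L]
  if (var %in% nonnormal) {
    test <- if (length(x0) && length(x1)) mann_whitney(x0, x1)$p_value else NA_real_
    fmt <- function(v) sprintf("%.0f (%.0f, %.0f)", median(v),
                               quantile(v, 0.25), quantile(v, 0.75))
    list(summary0 = fmt(x0), summary1 = fmt(x1), p = test,
         test = "mann-whitney")
  } else {
    test <- if (length(x0) > 1 && length(x1) > 1)
      t_test_raw(x0, x1)$p_value else NA_real_
    fmt <- function(v) sprintf("%.2f +/- %.2f", mean(v), sd(v))
    list(summary0 = fmt(x0), summary1 = fmt(x1), p = test, test = "t")
  }
}

summarize_categorical <- function(x, g) {
  tab <- table(factor(x), factor(g, levels = c(0, 1)))
  p <- if (all(dim(tab) >= 2) && !any(rowSums(tab) == 0) && !any(colSums(tab) == 0)) {
    chi_square(unclass(tab))$p_value
  } else NA_real_
  fmt <- function(col) {
    n <- tab[, col]
    paste(sprintf("%s %d (%.1f%%)", rownames(tab), n,
                  100 * n / pmax(1, rowSums(tab))), collapse = "; ")
  }
  list(summary0 = fmt("0"), summary1 = fmt("1"), p = p, test = "chi-square/fisher")
}

#' Cohort summary ("table one")
#'
#' Per-variable summaries of a cohort split by recurrence status, with the
#' test chosen by variable type: Student t (mean +/- SD) for continuous
#' variables, Mann-Whitney (median, IQR) for score-like variables listed in
#' `nonnormal`, and chi-square/Fisher for categoricals. With `strata`, the
#' report is computed within each stratum (e.g. stroke subtype). Groups
#' with a single class yield summaries with the tests skipped (p = NA).
#'
#' @param cohort data.frame of subject records (e.g. the `clinical` slot of
#'   a [generate_cohort()] result).
#' @param group name of the binary 0/1 grouping column (default
#'   `"recurrence"`).
#' @param variables columns to summarise (default: all except identifiers,
#'   the group, and generator-internal columns).
#' @param strata optional stratification column name (e.g. `"toast_subtype"`).
#' @param nonnormal variables summarised as median (IQR) with Mann-Whitney.
#' @return data.frame with columns `variable`, `stratum`, `summary_group0`,
#'   `summary_group1`, `test`, `p_value`, `p_formatted`.
#' @export
table_one <- function(cohort, group = "recurrence", variables = NULL,
                      strata = NULL, nonnormal = TABLEONE_NONNORMAL) {
  if (!nrow(cohort)) stop("empty cohort")
  if (!group %in% names(cohort)) stop("grouping column not found: ", group)
  drop_cols <- c("id", group, strata, "days_to_recurrence", "true_probability")
  variables <- variables %||% setdiff(names(cohort), drop_cols)
  strata_vals <- if (is.null(strata)) "(all)" else unique(as.character(cohort[[strata]]))
  rows <- list()
  for (s in strata_vals) {
    sub <- if (is.null(strata)) cohort else cohort[cohort[[strata]] == s, , drop = FALSE]
    g <- as.integer(sub[[group]])
    single_class <- length(unique(g)) < 2L
    for (v in variables) {
      x <- sub[[v]]
      is_cat <- is.character(x) || is.factor(x) || is.logical(x) ||
        (is.numeric(x) && all(x %in% c(0, 1)) && !(v %in% nonnormal))
      res <- if (single_class) {
        list(summary0 = NA_character_, summary1 = NA_character_,
             p = NA_real_, test = "skipped (single class)")
      } else if (is_cat) {
        summarize_categorical(x, g)
      } else {
        summarize_continuous(x, g, v, nonnormal)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratum = s,
        summary_group0 = res$summary0, summary_group1 = res$summary1,
        test = res$test, p_value = res$p,
        p_formatted = if (is.na(res$p)) NA_character_ else format_pvalue(res$p),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
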