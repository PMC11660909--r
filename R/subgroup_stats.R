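# Subgroup characterisation: differences in means/proportions with 95%
# CIs and Mann-Whitney comparisons, mirroring the summary-table style of
# observational subtype analyses.

new_difference_row <- function(variable, estimate, ci_low, ci_high,
                               degenerate = FALSE) {
  tibble::tibble(
    variable = variable, estimate = estimate,
    ci_low = ci_low, ci_high = ci_high,
    significant = (ci_low > 0 | ci_high < 0) & !degenerate,
    degenerate = degenerate
  )
}

#' Difference in means with a Welch normal-approximation CI
#'
#' Estimate `m1 - m2` with CI `estimate +/- z * sqrt(s1^2/n1 + s2^2/n2)`.
#'
#' @param n1,m1,s1 size, mean, SD of group 1.
#' @param n2,m2,s2 size, mean, SD of group 2.
#' @param level confidence level.
#' @param variable label carried into the output row.
#' @return one-row tibble: estimate, ci_low, ci_high, significance flag
#'   (CI excludes 0), and a `degenerate` flag for zero-variance inputs at
#'   small n.
#' @export
mean_diff_ci <- function(n1, m1, s1, n2, m2, s2, level = 0.95,
                         variable = "value") {
  if (n1 < 2 || n2 < 2) stopf("need n >= 2 in both groups")
  if (s1 < 0 || s2 < 0) stopf("negative SD")
  z <- qnorm(1 - (1 - level) / 2)
  est <- m1 - m2
  se <- sqrt(s1^2 / n1 + s2^2 / n2)
  degenerate <- se == 0 && (n1 < 30 || n2 < 30)
  new_difference_row(variable, est, est - z * se, est + z * se, degenerate)
}

#' Difference in proportions with a Wald CI, in percentage points
#'
#' Estimate `p2 - p1` (percentage points) with Wald CI
#' `estimate +/- z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`.
#'
#' @param p1,n1 proportion and size of group 1.
#' @param p2,n2 proportion and size of group 2.
#' @param level confidence level.
#' @param variable label carried into the output row.
#' @return one-row tibble as in [mean_diff_ci()]; a zero-width Wald CI
#'   (boundary proportions) is flagged degenerate.
#' @export
prop_diff_ci <- function(p1, n1, p2, n2, level = 0.95,
                         variable = "proportion") {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) {
    stopf("proportions must lie in [0, 1]")
  }
  if (n1 < 1 || n2 < 1) stopf("need n >= 1 in both groups")
  z <- qnorm(1 - (1 - level) / 2)
  est <- (p2 - p1) * 100
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) * 100
  new_difference_row(variable, est, est - z * se, est + z * se,
                     degenerate = se == 0)
}

#' Mann-Whitney U test
#'
#' Exact p-value by enumeration when `min(n) <= 8` and there are no ties,
#' normal approximation with tie correction otherwise (both delegated to
#' [stats::wilcox.test]); two samples with all values tied return p = 1.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `U` (statistic for `x`) and `p_value` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stopf("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  }
  exact <- min(length(x), length(y)) <= 8 && !has_ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  list(U = unname(ht$statistic), p_value = min(ht$p.value, 1))
}

is_binary <- function(v) {
  v <- v[!is.na(v)]
  if (is.logical(v)) return(TRUE)
  u <- unique(v)
  length(u) <= 2 && (all(u %in% c(0, 1)) || is.character(v) || is.factor(v))
}

#' Characterise progression subgroups on baseline variables
#'
#' Applies [mean_diff_ci()] to numeric variables and [prop_diff_ci()] to
#' binary ones, comparing fast vs slow progressors (estimates are
#' fast - slow; proportions in percentage points). Variables with fewer
#' than 2 observations per group are skipped with a warning.
#'
#' @param baseline baseline feature table with a `patient_id` column.
#' @param assignment an `assignment` carrying a slow/fast semantic map.
#' @param variables variables to compare; defaults to every column except
#'   `patient_id`.
#' @return tibble of difference rows (see [mean_diff_ci()]), with a
#'   `type` column (`"mean"` or `"proportion"`).
#' @export
characterize <- function(baseline, assignment,
                         variables = setdiff(names(baseline), "patient_id")) {
  stopifnot(inherits(assignment, "assignment"))
  idx <- match(baseline$patient_id, assignment$patient_id)
  if (anyNA(idx)) stopf("assignment does not cover all baseline patients")
  grp <- assignment$semantic_label[idx]
  if (length(unique(grp)) < 2) {
    warning("only one subgroup present; returning empty table")
    return(tibble::tibble())
  }
  rows <- list()
  for (v in variables) {
    col <- baseline[[v]]
    ok <- !is.na(col)
    n_fast <- sum(ok & grp == "fast"); n_slow <- sum(ok & grp == "slow")
    if (n_fast < 2 || n_slow < 2) {
      warning(sprintf("variable %s has < 2 observations per group; skipped", v))
      next
    }
    if (is_binary(col)) {
      val <- if (is.character(col) || is.factor(col)) {
        as.numeric(col == sort(unique(as.character(col[ok])))[1])
      } else as.numeric(col)
      r <- prop_diff_ci(mean(val[ok & grp == "slow"]), n_slow,
                        mean(val[ok & grp == "fast"]), n_fast,
                        variable = v)
      r$type <- "proportion"
    } else {
      r <- mean_diff_ci(n_fast, mean(col[ok & grp == "fast"]),
                        sd(col[ok & grp == "fast"]),
                        n_slow, mean(col[ok & grp == "slow"]),
                        sd(col[ok & grp == "slow"]),
                        variable = v)
      r$type <- "mean"
    }
    rows[[length(rows) + 1]] <- r
  }
  if (length(rows) == 0) return(tibble::tibble())
  dplyr::bind_rows(rows)
}
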