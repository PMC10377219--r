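#' Two-sample Welch t-test
#'
#' Two-sided unequal-variance (Welch) location test used to screen the
#' continuous candidate variables against the two stress groups.
#'
#' @param a,b Numeric samples, each with at least 2 values and positive
#'   variance.
#' @return List with `statistic` (Welch t) and `p_value`.
#' @examples
#' two_sample_t_test(rnorm(50), rnorm(50, mean = 1))
#' @export
two_sample_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("statistical degeneracy: each sample needs at least 2 values",
         call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  if (stats::var(a) <= 0 || stats::var(b) <= 0)
    stop("statistical degeneracy: zero-variance sample", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Test of independence between a binary lifestyle variable (rows) and the
#' stress group (columns), computed WITHOUT Yates continuity correction with
#' 1 degree of freedom: only the uncorrected statistic reproduces the
#' published p-values for the gender, drinking and smoking tables.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive row and column
#'   margins.
#' @return List with `statistic` (Pearson X-squared) and `p_value` (upper
#'   chi-square tail, df = 1).
#' @examples
#' gender <- matrix(c(289, 351, 228, 405), nrow = 2)  # cols = low/high stress
#' chi_square_test(gender)$p_value                    # rounds to 0.001
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("contingency table must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("contingency table must hold nonnegative finite counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("statistical degeneracy: zero margin in contingency table",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

split_by_group <- function(cohort, v) {
  split(as.numeric(cohort[[v]]), cohort$stress)
}

check_two_groups <- function(cohort) {
  if (!nrow(cohort))
    stop("cohort is empty", call. = FALSE)
  if (!all(c("low", "high") %in% cohort$stress))
    stop("cohort must contain both stress groups", call. = FALSE)
  invisible(cohort)
}

test_variable <- function(cohort, v) {
  if (v %in% continuous_vars()) {
    s <- split_by_group(cohort, v)
    r <- tryCatch(two_sample_t_test(s$low, s$high),
                  error = function(e) stop("variable '", v, "': ",
                                           conditionMessage(e), call. = FALSE))
    c(r, kind = "t")
  } else {
    tab <- table(cohort[[v]], cohort$stress)[, c("low", "high"), drop = FALSE]
    r <- tryCatch(chi_square_test(tab),
                  error = function(e) stop("variable '", v, "': ",
                                           conditionMessage(e), call. = FALSE))
    c(r, kind = "chi-square")
  }
}

#' Group summary table with screening p-values
#'
#' Per-group means of the eight continuous candidates and per-group
#' second-category counts of the three binary candidates, with each
#' variable's screening test p-value appended, in the fixed schema order
#' (the layout of the published group-comparison table).
#'
#' @param cohort A cohort tibble with both stress groups.
#' @return A tibble with columns `variable`, `kind`, `low`, `high`
#'   (group means for continuous variables, second-category counts for binary
#'   ones), `statistic` and `p_value`.
#' @export
group_summary <- function(cohort) {
  check_two_groups(cohort)
  rows <- lapply(cohort_schema(), function(v) {
    r <- test_variable(cohort, v)
    if (r$kind == "t") {
      s <- split_by_group(cohort, v)
      lo <- mean(s$low); hi <- mean(s$high)
    } else {
      second <- binary_levels()[[v]][2]
      lo <- sum(cohort[[v]] == second & cohort$stress == "low")
      hi <- sum(cohort[[v]] == second & cohort$stress == "high")
    }
    tibble::tibble(variable = v, kind = r$kind, low = lo, high = hi,
                   statistic = r$statistic, p_value = r$p_value)
  })
  do.call(rbind, rows)
}

#' Screen candidate variables for association with stress
#'
#' Applies the Welch t-test to the eight continuous candidates and the
#' uncorrected Pearson chi-square test to the three binary candidates, and
#' selects every variable with `p < alpha`. No multiplicity correction is
#' applied. On cohorts generated from [default_cohort_spec()] the selected
#' set is typically the nine variables gender, age, height, weight, sleep
#' duration, pulse rate, SBP, drinking and smoking, with DBP and BMI
#' excluded.
#'
#' @param cohort A cohort tibble with both stress groups.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `screening_report`: list with `tests` (tibble
#'   of variable, kind, statistic, p_value, selected in schema order),
#'   `alpha`, and `selected` (character vector of selected variables).
#' @export
screen_features <- function(cohort, alpha = 0.05) {
  check_two_groups(cohort)
  stopifnot(is.numeric(alpha), alpha > 0, alpha <= 1)
  rows <- lapply(cohort_schema(), function(v) {
    r <- test_variable(cohort, v)
    tibble::tibble(variable = v, kind = r$kind, statistic = r$statistic,
                   p_value = r$p_value, selected = r$p_value < alpha)
  })
  tests <- do.call(rbind, rows)
  structure(list(tests = tests, alpha = alpha,
                 selected = tests$variable[tests$selected]),
            class = "screening_report")
}

# fixed-point 3-decimal formatting used in the printed summary (so very small
# p-values display as 0.000); full precision is retained in the report itself
format_p <- function(p) formatC(p, format = "f", digits = 3)

#' @export
print.screening_report <- function(x, ...) {
  cat("Feature screening at alpha =", x$alpha, "\n")
  df <- as.data.frame(x$tests)
  df$statistic <- round(df$statistic, 3)
  df$p_value <- format_p(df$p_value)
  print(df, row.names = FALSE)
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
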