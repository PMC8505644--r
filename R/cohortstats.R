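# Table-1-style group comparisons.
#
# Continuous variables are gated through a Shapiro-Wilk normality check in
# each group; both groups normal -> two-sample t-test, otherwise
# Kruskal-Wallis. Categorical variables use the chi-squared test of
# independence with Yates continuity correction (the R default for 2x2
# tables).

#' Shapiro-Wilk normality gate
#'
#' Returns `TRUE` when the sample is compatible with normality at the 0.05
#' level (Shapiro-Wilk p >= 0.05). A degenerate (essentially constant)
#' vector returns `FALSE` with a warning rather than an error.
#'
#' @param x numeric vector, 3 <= length <= 5000 after removing NAs.
#' @return logical scalar.
#' @export
normality_gate <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  assert_that(n >= 3 && n <= 5000,
              "normality gate supports 3 <= n <= 5000 non-missing values")
  if (stats::sd(x) == 0 || diff(range(x)) < .Machine$double.eps^0.5) {
    warning("essentially constant sample; treating as non-normal",
            call. = FALSE)
    return(FALSE)
  }
  stats::shapiro.test(x)$p.value >= 0.05
}

#' Compare a continuous variable between two groups
#'
#' If both groups pass [normality_gate()], a two-sample t-test is used;
#' otherwise a Kruskal-Wallis test. The test actually used is recorded in
#' the result. Group summaries are mean (SD).
#'
#' @param x_case,x_control numeric vectors (NAs dropped), each with >= 2
#'   non-missing values.
#' @param variable optional variable name carried into the result.
#' @return data frame with one row: `variable`, `test`, `statistic`, `p`,
#'   `mean_case`, `sd_case`, `mean_control`, `sd_control`,
#'   `n_case`, `n_control`.
#' @export
compare_continuous <- function(x_case, x_control, variable = NA_character_) {
  x_case <- x_case[!is.na(x_case)]
  x_control <- x_control[!is.na(x_control)]
  assert_that(length(x_case) >= 2 && length(x_control) >= 2,
              "each group needs >= 2 non-missing values")
  all_tied <- stats::sd(c(x_case, x_control)) == 0
  normal <- !all_tied &&
    suppressWarnings(normality_gate(x_case) && normality_gate(x_control))
  if (normal) {
    ht <- stats::t.test(x_case, x_control)
    test <- "t"
  } else if (all_tied) {
    # both groups identical constants: no evidence of a difference
    ht <- list(statistic = 0, p.value = 1)
    test <- "kruskal-wallis"
  } else {
    ht <- stats::kruskal.test(list(x_case, x_control))
    test <- "kruskal-wallis"
  }
  data.frame(variable = variable, test = test,
             statistic = unname(ht$statistic), p = ht$p.value,
             mean_case = mean(x_case), sd_case = stats::sd(x_case),
             mean_control = mean(x_control), sd_control = stats::sd(x_control),
             n_case = length(x_case), n_control = length(x_control),
             stringsAsFactors = FALSE)
}

#' Compare a categorical variable between two groups (2x2)
#'
#' Chi-squared test of independence on a 2x2 count table, with Yates
#' continuity correction by default.
#'
#' @param table 2x2 matrix of non-negative integer counts, rows = groups,
#'   columns = category levels.
#' @param correct apply Yates continuity correction (default `TRUE`).
#' @param variable optional variable name carried into the result.
#' @return data frame with one row: `variable`, `test`, `statistic`, `p`,
#'   counts and within-group percentages of the first column.
#' @export
compare_categorical <- function(table, correct = TRUE,
                                variable = NA_character_) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2, 2)), "expected a 2x2 count table")
  assert_that(all(table >= 0), "counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_hpameth("zero margin in 2x2 table; test undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  data.frame(variable = variable, test = "chi-squared",
             statistic = unname(ht$statistic), p = ht$p.value,
             k_case = table[1, 1], n_case = sum(table[1, ]),
             pct_case = 100 * table[1, 1] / sum(table[1, ]),
             k_control = table[2, 1], n_control = sum(table[2, ]),
             pct_control = 100 * table[2, 1] / sum(table[2, ]),
             stringsAsFactors = FALSE)
}

#' Group-comparison table for a phenotype data frame
#'
#' Runs [compare_continuous()] on every numeric non-binary variable and
#' [compare_categorical()] on every binary variable, contrasting the two
#' levels of `group`.
#'
#' @param pheno phenotype data frame.
#' @param group name of the binary grouping column (1 = case).
#' @param exclude column names to skip (ids etc.); the group column is
#'   always skipped.
#' @return data frame, one row per variable.
#' @export
cohort_table1 <- function(pheno, group = "dst_ns",
                          exclude = "sample_id") {
  assert_that(group %in% colnames(pheno), sprintf("no column '%s'", group))
  g <- pheno[[group]]
  vars <- setdiff(colnames(pheno), c(group, exclude))
  rows <- lapply(vars, function(v) {
    x <- pheno[[v]]
    is_binary <- all(x %in% c(0, 1, NA))
    if (is_binary) {
      tab <- rbind(c(sum(x == 1 & g == 1, na.rm = TRUE),
                     sum(x == 0 & g == 1, na.rm = TRUE)),
                   c(sum(x == 1 & g == 0, na.rm = TRUE),
                     sum(x == 0 & g == 0, na.rm = TRUE)))
      out <- try(compare_categorical(tab, variable = v), silent = TRUE)
      if (inherits(out, "try-error")) return(NULL)
      out[, c("variable", "test", "statistic", "p")]
    } else {
      out <- compare_continuous(x[g == 1], x[g == 0], variable = v)
      out[, c("variable", "test", "statistic", "p")]
    }
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
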