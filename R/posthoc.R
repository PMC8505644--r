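# Post-hoc interaction models.
#
# Checks whether the methylation/DST association is disease-state
# dependent: a linear model of the CpG M-value on two binary factors and
# their product (CpG ~ a + b + a:b), and a logistic model of the binary
# outcome on methylation, diagnosis, and their product
# (outcome ~ cg + b + cg:b).

interaction_result <- function(form, cf, n, converged = TRUE,
                               separation = FALSE) {
  structure(list(model = form,
                 coefficients = cf[, 1],
                 se = cf[, 2],
                 statistic = cf[, 3],
                 p = cf[, 4],
                 n = n,
                 converged = converged,
                 separation = separation),
            class = "interaction_fit")
}

#' Linear interaction model of methylation on two binary factors
#'
#' OLS of the CpG M-values on `a + b + a:b` with t-based p-values. All
#' four cells of the 2x2 factor layout must be occupied, otherwise the
#' interaction is inestimable.
#'
#' @param cg numeric M-value vector.
#' @param a,b binary (0/1) vectors of the same length.
#' @return `interaction_fit`: coefficients (intercept, a, b, a:b), their
#'   SEs, t-statistics and p-values, and `n`.
#' @export
interaction_linear <- function(cg, a, b) {
  assert_that(length(cg) == length(a) && length(cg) == length(b),
              "inputs must have equal length")
  assert_that(all(a %in% 0:1) && all(b %in% 0:1),
              "a and b must be binary 0/1")
  cells <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  if (any(cells == 0)) {
    stop_hpameth("empty cell in the 2x2 factor layout: interaction inestimable")
  }
  fit <- stats::lm(cg ~ a * b)
  cf <- summary(fit)$coefficients
  interaction_result("linear", cf, length(cg))
}

#' Logistic interaction model of a binary outcome on methylation
#'
#' Binomial GLM (iteratively reweighted least squares) of `outcome` on
#' `cg + b + cg:b`, with Wald p-values. Complete or quasi-complete
#' separation -- fitted probabilities collapsing to 0/1 or a diverging
#' coefficient -- is detected and raised as an error rather than returned
#' as a silently divergent fit; plain non-convergence is flagged in the
#' result.
#'
#' @param outcome binary (0/1) vector with both levels present.
#' @param cg numeric M-value vector.
#' @param b binary (0/1) vector.
#' @return `interaction_fit`: coefficients (intercept, cg, b, cg:b), SEs,
#'   z-statistics, p-values, `n`, `converged`.
#' @export
interaction_logistic <- function(outcome, cg, b) {
  assert_that(length(outcome) == length(cg) && length(outcome) == length(b),
              "inputs must have equal length")
  assert_that(all(outcome %in% 0:1) && length(unique(outcome)) == 2,
              "outcome must be binary 0/1 with both levels present")
  assert_that(all(b %in% 0:1), "b must be binary 0/1")
  fit <- suppressWarnings(
    stats::glm(outcome ~ cg * b, family = stats::binomial(),
               control = stats::glm.control(maxit = 50, epsilon = 1e-10))
  )
  mu <- stats::fitted(fit)
  coef_norm <- max(abs(stats::coef(fit)), na.rm = TRUE)
  separated <- all(abs(mu - outcome) < 1e-6) || coef_norm > 15
  if (separated) {
    stop_hpameth("separation detected in logistic interaction model; coefficients diverge")
  }
  cf <- summary(fit)$coefficients
  interaction_result("logistic", cf, length(outcome),
                     converged = fit$converged)
}
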