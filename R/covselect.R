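# Forward covariate selection via nested-model ANOVA.
#
# To avoid over-fitting small cohorts, each candidate clinical covariate is
# admitted into the phenotype model only if adding it significantly improves
# the fit (nested-model F-test p < alpha, default 0.10). Selection is
# classic greedy forward: at each step every remaining candidate is tested
# against the current model, the smallest-p candidate is added if it
# qualifies, and the full evaluation trace is kept so the single-step view
# ("each candidate tested alone") can also be read off step 1.

#' Greedy forward covariate selection
#'
#' @param y outcome vector (continuous or 0/1; modelled with `lm` either
#'   way by default, matching common practice for these screens; set
#'   `family = "logistic"` for a deviance-based variant).
#' @param candidates data frame or matrix of candidate covariates, columns
#'   named; may have zero columns.
#' @param alpha inclusion threshold on the nested-test p-value.
#'   Default 0.10.
#' @param family `"linear"` (nested ANOVA F-test) or `"logistic"`
#'   (binomial GLM, likelihood-ratio chi-squared test).
#' @return list of class `selection_trace`: `selected` (character vector,
#'   in order of entry), `trace` (data frame: `step`, `candidate`,
#'   `statistic`, `p`, `accepted`), `alpha`.
#' @export
forward_select <- function(y, candidates, alpha = 0.10,
                           family = c("linear", "logistic")) {
  family <- match.arg(family)
  candidates <- as.data.frame(candidates)
  assert_that(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  if (ncol(candidates) > 0) {
    assert_that(length(y) == nrow(candidates),
                "y and candidates must have the same length")
    assert_that(length(y) >= ncol(candidates) + 2,
                "need n >= number of candidates + 2")
  }
  remaining <- sort(colnames(candidates))
  selected <- character(0)
  trace <- list()
  step <- 0L

  test_candidate <- function(cand) {
    dat <- data.frame(.y = y, candidates[, c(selected, cand), drop = FALSE])
    base_terms <- if (length(selected)) paste(selected, collapse = " + ") else "1"
    f0 <- stats::as.formula(paste(".y ~", base_terms))
    f1 <- stats::as.formula(paste(".y ~", base_terms, "+", cand))
    if (family == "linear") {
      m0 <- stats::lm(f0, data = dat)
      m1 <- stats::lm(f1, data = dat)
      if (m1$rank <= m0$rank) {
        stop_hpameth(sprintf("singular design: candidate '%s' adds no rank", cand))
      }
      a <- stats::anova(m0, m1)
      c(statistic = a$F[2], p = a$`Pr(>F)`[2])
    } else {
      m0 <- stats::glm(f0, data = dat, family = stats::binomial())
      m1 <- stats::glm(f1, data = dat, family = stats::binomial())
      if (m1$rank <= m0$rank) {
        stop_hpameth(sprintf("singular design: candidate '%s' adds no rank", cand))
      }
      a <- stats::anova(m0, m1, test = "Chisq")
      c(statistic = a$Deviance[2], p = a$`Pr(>Chi)`[2])
    }
  }

  repeat {
    if (length(remaining) == 0) break
    step <- step + 1L
    res <- t(vapply(remaining, test_candidate, numeric(2)))
    best <- remaining[order(res[, "p"], remaining)][1]
    accept <- is.finite(res[best, "p"]) && res[best, "p"] < alpha
    trace[[step]] <- data.frame(step = step, candidate = remaining,
                                statistic = unname(res[, "statistic"]),
                                p = unname(res[, "p"]),
                                accepted = remaining == best & accept,
                                stringsAsFactors = FALSE, row.names = NULL)
    if (!accept) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }

  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), candidate = character(0),
               statistic = numeric(0), p = numeric(0),
               accepted = logical(0))
  structure(list(selected = selected, trace = trace_df, alpha = alpha,
                 family = family),
            class = "selection_trace")
}

#' Default candidate covariate names for the DST phenotype screen
#'
#' The clinical variables screened as potential confounders of the
#' methylation/DST association: hypersexuality, depression, childhood-trauma
#' total, TSH/T4 ratio, HbA1c, baseline cortisol and ACTH, testosterone,
#' TNF-alpha and IL-6.
#'
#' @return character vector of column names.
#' @export
default_covariate_candidates <- function() {
  c("hypersexuality", "depression", "ctq_total", "tsh_t4", "hba1c",
    "cortisol_baseline", "acth_baseline", "testosterone", "tnf_alpha", "il6")
}
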