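# Methylation-expression correlation in independent cohorts.
#
# Candidate probes are tested for a relation between promoter methylation
# (M-values, averaged across a transcript's probes when there are several)
# and the gene's normalized expression, sample by sample, with two
# complementary estimators: Pearson product-moment correlation and an
# MM-type robust simple regression. The robust route guards the very small
# cohorts (n = 10-11) against single outliers and heteroscedasticity.

#' Average M-values over a probe set
#'
#' Arithmetic mean across the listed probes, per sample.
#'
#' @param m probes-by-samples M-value matrix.
#' @param probes non-empty character vector of probe ids present in `m`.
#' @return named per-sample numeric vector.
#' @export
average_probes <- function(m, probes) {
  assert_that(length(probes) >= 1, "probe list must be non-empty")
  missing <- setdiff(probes, rownames(m))
  if (length(missing) > 0) {
    stop_hpameth(sprintf("probe(s) not in matrix: %s",
                         paste(missing, collapse = ", ")))
  }
  colMeans(m[probes, , drop = FALSE])
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @return list with `r` and two-sided `p`.
#' @export
pearson_cor <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 3, "need n >= 3")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "constant input: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' MM-type robust simple regression
#'
#' High-breakdown S-estimate start followed by bisquare IRLS refinement at
#' ~90% normal efficiency (tuning constant 3.88), via [MASS::rlm()] with
#' `method = "MM"`. The random subsampling of the S-stage runs under a
#' fixed local seed, so results are deterministic and the caller's RNG
#' stream is untouched. The p-value is a Wald test of the slope on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 5.
#' @param seed local seed for the S-estimate subsampling.
#' @param maxit IRLS iteration cap; non-convergence is an error, not
#'   silent.
#' @return list with `coefficient` (slope), `se`, `t`, `p`, `intercept`.
#' @export
robust_fit <- function(x, y, seed = 20041L, maxit = 200L) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 5, "robust fit needs n >= 5")
  # exactly linear data has zero residual scale, which the S-estimate
  # cannot handle; the OLS line is then the exact robust fit too
  ols <- stats::lm.fit(cbind(1, x), y)
  if (max(abs(ols$residuals)) < 1e-10 * (stats::sd(y) + 1)) {
    return(list(coefficient = unname(ols$coefficients[2]), se = 0,
                t = Inf, p = 0,
                intercept = unname(ols$coefficients[1])))
  }
  fit <- with_local_seed(seed, {
    MASS::rlm(y ~ x, method = "MM", psi = MASS::psi.bisquare, c = 3.88,
              maxit = maxit)
  })
  if (!fit$converged) {
    stop_hpameth(sprintf("robust IRLS did not converge in %d iterations", maxit))
  }
  cf <- summary(fit)$coefficients
  tval <- cf["x", "t value"]
  p <- 2 * stats::pt(-abs(tval), df = length(x) - 2)
  list(coefficient = unname(cf["x", "Value"]),
       se = unname(cf["x", "Std. Error"]),
       t = unname(tval), p = p,
       intercept = unname(cf["(Intercept)", "Value"]))
}

#' Correlate transcript methylation with gene expression in a cohort
#'
#' For each transcript of `mapping`, averages the M-values of its probes
#' (when more than one), then runs both [pearson_cor()] and [robust_fit()]
#' against the gene's expression across the samples shared between the two
#' matrices.
#'
#' @param meth probes-by-samples M-value matrix.
#' @param expr genes-by-samples expression matrix (one normalized value per
#'   gene and sample).
#' @param mapping data frame with columns `transcript`, `gene`, `probe_id`.
#' @param cohort_label label copied into every output row.
#' @return data frame, one row per transcript: `gene`, `transcript`,
#'   `n_probes`, `cohort`, `n_samples`, `pearson_r`, `pearson_p`,
#'   `robust_coef`, `robust_p`.
#' @export
correlate_cohort <- function(meth, expr, mapping, cohort_label = "cohort") {
  shared <- intersect(colnames(meth), colnames(expr))
  if (length(shared) < 3) {
    stop_hpameth("fewer than 3 samples shared between methylation and expression")
  }
  transcripts <- unique(mapping$transcript)
  rows <- lapply(transcripts, function(tr) {
    sub <- mapping[mapping$transcript == tr, , drop = FALSE]
    gene <- sub$gene[1]
    if (!gene %in% rownames(expr)) {
      stop_hpameth(sprintf("gene '%s' absent from expression matrix", gene))
    }
    x <- average_probes(meth[, shared, drop = FALSE], sub$probe_id)
    y <- expr[gene, shared]
    pe <- pearson_cor(x, y)
    rb <- robust_fit(x, y)
    data.frame(gene = gene, transcript = tr, n_probes = nrow(sub),
               cohort = cohort_label, n_samples = length(shared),
               pearson_r = pe$r, pearson_p = pe$p,
               robust_coef = rb$coefficient, robust_p = rb$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
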