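# Beta <-> M transformation and PCA-based sample QC.
#
# Beta values are methylation fractions in [0,1]; the analysis scale is the
# M-value, M = log2(beta / (1 - beta)), whose sampling variance is far more
# homoscedastic across the beta range. Matrices carry their scale in the
# "meth_scale" attribute ("beta" or "M") so accidental double transformation
# is caught.

meth_scale <- function(m) {
  s <- attr(m, "meth_scale")
  if (is.null(s)) {
    # untagged matrix: infer from the value range
    s <- if (all(is.finite(m)) && min(m) >= 0 && max(m) <= 1) "beta" else "M"
  }
  s
}

set_meth_scale <- function(m, scale) {
  attr(m, "meth_scale") <- scale
  m
}

#' Convert beta values to M-values
#'
#' `M = log2(b / (1 - b))` after clipping `b` into `[eps, 1 - eps]` so that
#' boundary betas do not map to infinities. Elementwise and shape-preserving;
#' strictly monotone away from the clipped tails.
#'
#' @param beta numeric matrix (or vector) of beta values in \[0, 1\].
#' @param eps clipping bound, in (0, 0.5). Default `1e-6`.
#' @return object of the same shape on the M scale.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  assert_that(eps > 0 && eps < 0.5, "eps must lie in (0, 0.5)")
  if (identical(meth_scale(beta), "M")) {
    stop_hpameth("input is already on the M scale")
  }
  assert_that(all(beta >= 0 & beta <= 1, na.rm = TRUE),
              "beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  m <- log2(b / (1 - b))
  attributes(m) <- attributes(beta)
  set_meth_scale(m, "M")
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()] away from the clipped tails:
#' `b = 2^M / (1 + 2^M)`.
#'
#' @param m numeric matrix (or vector) of M-values.
#' @return object of the same shape on the beta scale.
#' @export
m_to_beta <- function(m) {
  b <- 1 / (1 + 2^(-m))
  attributes(b) <- attributes(m)
  set_meth_scale(b, "beta")
}

#' Flag sample outliers on the first principal component
#'
#' Probes whose beta-value standard deviation exceeds `sd_threshold` (a
#' variability filter: near-constant probes carry no sample-level signal)
#' enter a PCA of the centred probe-by-sample matrix. Samples whose PC1
#' score falls outside `mean +/- z * SD` of the PC1 scores are flagged,
#' where `z` is the two-sided normal quantile of the `ref_range` reference
#' range (1.96 for 95%). This replaces visual inspection of the PC1 display
#' with a reproducible rule.
#'
#' @param beta probes-by-samples matrix of beta values.
#' @param sd_threshold per-probe beta SD inclusion threshold. Default 0.2.
#' @param ref_range central reference range for the flagging rule, in (0,1).
#'   Default 0.95.
#' @return list of class `outlier_report`: `pc1_variance_pct`,
#'   `variance_pct` (all PCs), `scores` (named PC1 scores), `flagged`
#'   (named logical), `probes_used`, `sd_threshold`, `ref_range`.
#' @export
pca_outlier_flags <- function(beta, sd_threshold = 0.2, ref_range = 0.95) {
  assert_that(ncol(beta) >= 3, "need at least 3 samples for outlier PCA")
  assert_that(ref_range > 0 && ref_range < 1, "ref_range must lie in (0,1)")
  sds <- apply(beta, 1, stats::sd)
  use <- which(sds > sd_threshold)
  if (length(use) == 0) {
    stop_hpameth(sprintf(
      "no probe exceeds the beta-SD threshold %.3g; cannot run outlier PCA",
      sd_threshold))
  }
  x <- t(beta[use, , drop = FALSE])           # samples x probes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1]
  names(scores) <- colnames(beta)
  z <- stats::qnorm(1 - (1 - ref_range) / 2)
  ctr <- mean(scores)
  s <- stats::sd(scores)
  flagged <- abs(scores - ctr) > z * s
  structure(list(pc1_variance_pct = var_pct[1],
                 variance_pct = var_pct,
                 scores = scores,
                 flagged = flagged,
                 probes_used = length(use),
                 sd_threshold = sd_threshold,
                 ref_range = ref_range),
            class = "outlier_report")
}

#' Regress nuisance covariates out of M-values
#'
#' Generic hook for, e.g., estimated cell-type fractions: each probe's
#' M-values are replaced by intercept + residuals of an OLS fit on the
#' supplied covariates. No reference-based deconvolution is performed.
#'
#' @param m probes-by-samples M-value matrix.
#' @param covariates samples-by-k numeric matrix/data frame, rows aligned
#'   with `colnames(m)`.
#' @return adjusted matrix of the same shape.
#' @export
regress_out <- function(m, covariates) {
  cov <- as.matrix(covariates)
  assert_that(nrow(cov) == ncol(m),
              "covariate rows must match methylation samples")
  X <- cbind(Intercept = 1, cov)
  fit <- stats::lm.fit(X, t(m))
  adj <- t(fit$residuals) + rowMeans(m)
  dimnames(adj) <- dimnames(m)
  set_meth_scale(adj, "M")
}
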