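# Per-CpG linear modelling with empirical-Bayes variance moderation.
#
# Each probe's M-values are regressed on the phenotype of interest plus
# selected covariates. With tens of probes and ~90 samples, per-probe
# residual variances are noisy; they are shrunk toward a common prior by
# the hierarchical model of Smyth (2004, SAGMB 3:1, "Linear models and
# empirical Bayes methods..."): s2_g | sigma2_g ~ sigma2_g * chisq(d_g)/d_g
# and 1/sigma2_g ~ chisq(d0)/(d0*s02). The posterior variance
# s2_post = (d0*s02 + d_g*s2_g) / (d0 + d_g) yields a moderated t-statistic
# with d0 + d_g degrees of freedom. The prior (d0, s02) is estimated by
# matching moments of log s2_g, which requires inverting the trigamma
# function. This machinery is implemented here in closed form; it is the
# computational core of the package.

#' Per-probe ordinary least squares fits
#'
#' Fits the same design matrix to every probe of an M-value matrix and
#' returns, per probe, the coefficient of interest, its unscaled standard
#' deviation `u = sqrt([(X'X)^-1]_jj)`, the residual variance `s2`, and the
#' residual degrees of freedom.
#'
#' @param m probes-by-samples M-value matrix.
#' @param design samples-by-covariates numeric design matrix (including the
#'   intercept column), full rank, rows aligned with `colnames(m)`.
#' @param coef name (or index) of the design column of interest.
#' @return data frame: `probe_id`, `coef`, `u`, `s2`, `df`.
#' @export
fit_probes <- function(m, design, coef = 2L) {
  design <- as.matrix(design)
  assert_that(nrow(design) == ncol(m),
              "design rows must match methylation samples")
  if (!is.null(rownames(design)) && !is.null(colnames(m))) {
    assert_that(identical(rownames(design), colnames(m)),
                "sample ids of design and M matrix disagree")
  }
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) stop_hpameth("design matrix is rank deficient")
  n <- nrow(design)
  d <- n - qr_x$rank
  assert_that(d >= 1, "need residual degrees of freedom >= 1")
  if (is.character(coef)) {
    assert_that(coef %in% colnames(design),
                sprintf("no design column '%s'", coef))
    j <- match(coef, colnames(design))
  } else {
    j <- as.integer(coef)
  }
  fit <- stats::lm.fit(design, t(m))
  cf <- fit$coefficients
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1)   # single-probe input
  beta <- t(cf)[, j]
  res <- fit$residuals                       # samples x probes
  if (is.null(dim(res))) res <- matrix(res, ncol = 1)
  s2 <- colSums(res^2) / d
  xtx_inv <- chol2inv(qr.R(qr_x))
  u <- sqrt(xtx_inv[j, j])
  data.frame(probe_id = rownames(m), coef = unname(beta), u = u,
             s2 = unname(s2), df = d,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Inverse of the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on a
#' monotone-transformed scale, to a relative tolerance of 1e-8. Needed to
#' estimate the prior degrees of freedom of the variance hierarchy.
#'
#' @param y positive numeric vector.
#' @return numeric vector `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  assert_that(all(is.finite(y)) && all(y > 0), "y must be positive and finite")
  vapply(y, function(yi) {
    # asymptotic endpoints: trigamma(x) ~ 1/x for large x, ~ 1/x^2 near 0
    if (yi > 1e9) return(1 / sqrt(yi))
    if (yi < 1e-8) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in seq_len(100)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Estimate the variance prior by moment matching on log variances
#'
#' Given per-probe residual variances `s2` and degrees of freedom `df`,
#' estimates the prior degrees of freedom `d0` and prior variance `s02` of
#' the scaled-inverse-chi-squared hierarchy. Writing
#' `e_g = log(s2_g) - digamma(df_g/2) + log(df_g/2)`, the excess spread of
#' `e_g` over its sampling variance `trigamma(df_g/2)` identifies
#' `trigamma(d0/2)`; zero or negative excess spread means the variances are
#' consistent with a single value and `d0 = Inf`.
#'
#' @param s2 per-probe residual variances (>= 2 positive values required).
#' @param df per-probe residual degrees of freedom (scalar or vector).
#' @return list of class `variance_prior`: `d0`, `s02`.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) == 0) stop_hpameth("all residual variances are zero")
  assert_that(sum(ok) >= 2, "need >= 2 probes with positive variance")
  s2 <- s2[ok]
  df <- df[ok]
  G <- length(s2)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  target <- mean((e - ebar)^2 * G / (G - 1) - trigamma(df / 2))
  if (target > 0) {
    d0 <- 2 * trigamma_inverse(target)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(ebar)
  }
  structure(list(d0 = d0, s02 = s02), class = "variance_prior")
}

#' Moderated t-statistics from probe fits and a variance prior
#'
#' Shrinks each residual variance toward the prior,
#' `s2_post = (d0*s02 + df*s2) / (d0 + df)`, and forms
#' `t = coef / (u * sqrt(s2_post))` with `d0 + df` degrees of freedom
#' (standard normal in the `d0 = Inf` limit; the ordinary OLS t in the
#' `d0 = 0` limit). Two-sided p-values; Benjamini-Hochberg q-values.
#'
#' @param fits data frame from [fit_probes()].
#' @param prior list with `d0`, `s02` (see [estimate_prior()]), or `NULL`
#'   to estimate it from `fits`.
#' @return data frame: `probe_id`, `coef`, `s2`, `s2_post`, `t`,
#'   `df_total`, `p`, `q`; prior attached as attribute `prior`.
#' @export
moderated_t <- function(fits, prior = NULL) {
  if (is.null(prior)) prior <- estimate_prior(fits$s2, fits$df)
  d0 <- prior$d0
  s02 <- prior$s02
  assert_that(d0 >= 0, "prior df must be >= 0")
  assert_that(s02 > 0 || d0 == 0, "prior variance must be positive")
  s2_post <- if (is.infinite(d0)) {
    rep(s02, nrow(fits))
  } else {
    (d0 * s02 + fits$df * fits$s2) / (d0 + fits$df)
  }
  tstat <- fits$coef / (fits$u * sqrt(s2_post))
  df_total <- d0 + fits$df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(probe_id = fits$probe_id, coef = fits$coef,
                    s2 = fits$s2, s2_post = s2_post, t = tstat,
                    df_total = df_total, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Built-in phenotype model presets
#'
#' Covariate sets selected by the forward screen for each phenotype of
#' interest: the DST non-suppression model adjusts for hypersexuality and
#' baseline cortisol; the cortisol/ACTH models (baseline and post-DST)
#' carry no covariates; the TSH/T4-ratio model adjusts for hypersexuality
#' and IL-6.
#'
#' @param name one of `"dst"`, `"cortisol_baseline"`, `"cortisol_dst"`,
#'   `"acth_baseline"`, `"acth_dst"`, `"tsh_t4"`.
#' @return list with `phenotype` and `covariates`.
#' @export
dmp_preset <- function(name) {
  presets <- list(
    dst = list(phenotype = "dst_ns",
               covariates = c("hypersexuality", "cortisol_baseline")),
    cortisol_baseline = list(phenotype = "cortisol_baseline",
                             covariates = character(0)),
    cortisol_dst = list(phenotype = "cortisol_dst", covariates = character(0)),
    acth_baseline = list(phenotype = "acth_baseline",
                         covariates = character(0)),
    acth_dst = list(phenotype = "acth_dst", covariates = character(0)),
    tsh_t4 = list(phenotype = "tsh_t4",
                  covariates = c("hypersexuality", "il6"))
  )
  if (!name %in% names(presets)) {
    stop_hpameth(sprintf("unknown preset '%s'; available: %s", name,
                         paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

#' Differential-methylation analysis of one phenotype
#'
#' Composes [fit_probes()], [estimate_prior()], [moderated_t()] and
#' [bh_fdr()] for one phenotype model: each probe's M-values are the
#' response, the phenotype (binary or continuous) plus covariates are the
#' predictors. Samples with a missing value in any model variable are
#' dropped; the count is attached as attribute `n_dropped` and reported
#' with a message.
#'
#' @param m probes-by-samples M-value matrix, columns named by sample id.
#' @param phenotype name of the phenotype column in `pheno`.
#' @param pheno phenotype data frame with a `sample_id` column.
#' @param covariates character vector of covariate column names (possibly
#'   empty), or `NULL` with `preset` given.
#' @param preset optional preset name (see [dmp_preset()]); overrides
#'   `phenotype` and `covariates`.
#' @return moderated-fit data frame (see [moderated_t()]) with one row per
#'   probe; attributes `prior`, `n_used`, `n_dropped`.
#' @export
run_dmp <- function(m, phenotype, pheno, covariates = character(0),
                    preset = NULL) {
  if (!is.null(preset)) {
    ps <- dmp_preset(preset)
    phenotype <- ps$phenotype
    covariates <- ps$covariates
  }
  vars <- c(phenotype, covariates)
  missing_vars <- setdiff(vars, colnames(pheno))
  if (length(missing_vars) > 0) {
    stop_hpameth(sprintf("phenotype table lacks column(s): %s",
                         paste(missing_vars, collapse = ", ")))
  }
  assert_that("sample_id" %in% colnames(pheno),
              "phenotype table needs a sample_id column")
  shared <- intersect(colnames(m), pheno$sample_id)
  if (length(shared) == 0) {
    stop_hpameth("no shared samples between M matrix and phenotype table")
  }
  ph <- pheno[match(shared, pheno$sample_id), , drop = FALSE]
  complete <- stats::complete.cases(ph[, vars, drop = FALSE])
  n_dropped <- sum(!complete) + (ncol(m) - length(shared))
  if (n_dropped > 0) {
    message(sprintf("run_dmp: dropped %d sample(s) (missing model variables or unmatched ids)",
                    n_dropped))
  }
  ph <- ph[complete, , drop = FALSE]
  m_use <- m[, ph$sample_id, drop = FALSE]
  design <- stats::model.matrix(
    stats::as.formula(paste("~", paste(vars, collapse = " + "))), data = ph)
  rownames(design) <- ph$sample_id
  fits <- fit_probes(m_use, design, coef = colnames(design)[2])
  out <- moderated_t(fits, prior = NULL)
  attr(out, "n_used") <- nrow(ph)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "phenotype") <- phenotype
  attr(out, "covariates") <- covariates
  out
}
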