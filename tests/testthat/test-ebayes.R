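test_that("intercept-only fit returns sample mean and variance; perfect fit has zero residual variance", {
  set.seed(1)
  y <- rnorm(12)
  m <- matrix(y, nrow = 1, dimnames = list("p1", sprintf("S%02d", 1:12)))
  X <- matrix(1, 12, 1, dimnames = list(sprintf("S%02d", 1:12), "Intercept"))
  fit <- fit_probes(m, X, coef = 1)
  expect_equal(fit$coef, mean(y))
  expect_equal(fit$s2, var(y))
  expect_equal(fit$df, 11)
  expect_equal(fit$u, sqrt(1 / 12))

  x <- rnorm(10)
  m2 <- matrix(x, nrow = 1, dimnames = list("p1", sprintf("S%02d", 1:10)))
  X2 <- cbind(Intercept = 1, x = x)
  rownames(X2) <- colnames(m2)
  fit2 <- fit_probes(m2, X2, coef = "x")
  expect_equal(fit2$coef, 1, tolerance = 1e-10)
  expect_equal(fit2$s2, 0, tolerance = 1e-18)
})

test_that("fit_probes agrees with the normal-equations oracle on random designs", {
  set.seed(2)
  for (i in 1:20) {
    n <- 10
    X <- cbind(1, matrix(rnorm(n * 2), n))
    colnames(X) <- c("I", "a", "b")
    m <- matrix(rnorm(5 * n), nrow = 5,
                dimnames = list(paste0("p", 1:5), NULL))
    fit <- fit_probes(m, X, coef = "a")
    for (g in 1:5) {
      orc <- ols_oracle(m[g, ], X)
      expect_equal(fit$coef[g], orc$beta[["a"]], tolerance = 1e-10)
      expect_equal(fit$s2[g], orc$s2, tolerance = 1e-10)
      expect_equal(fit$u, rep(unname(orc$u[2]), 5), tolerance = 1e-10)
      expect_equal(fit$df[g], orc$df)
    }
  }
})

test_that("rank-deficient designs and misaligned samples are refused", {
  m <- matrix(rnorm(20), 2, dimnames = list(c("p1", "p2"), letters[1:10]))
  X <- cbind(1, rep(2, 10))
  expect_error(fit_probes(m, X), "rank deficient")
  X2 <- cbind(I = 1, x = rnorm(10))
  rownames(X2) <- rev(letters[1:10])
  expect_error(fit_probes(m, X2, coef = "x"), "sample ids")
})

test_that("trigamma_inverse hits known fixed points and round-trips to 1e-8", {
  expect_equal(trigamma_inverse(pi^2 / 6), 1, tolerance = 1e-8)
  expect_equal(trigamma_inverse(trigamma(5)), 5, tolerance = 1e-8)
  set.seed(3)
  y <- exp(runif(200, log(1e-3), log(1e3)))
  x <- trigamma_inverse(y)
  expect_true(all(abs(trigamma(x) - y) / y < 1e-8))
  expect_error(trigamma_inverse(-1), "positive")
})

test_that("identical variances drive the prior df to infinity; two probes do not crash", {
  pr <- estimate_prior(rep(0.05, 100), df = 89)
  expect_equal(pr$d0, Inf)
  # log-scale bias correction leaves a ~1/df factor on degenerate input
  expect_equal(pr$s02, 0.05, tolerance = 0.02)
  pr2 <- estimate_prior(c(0.02, 0.08), df = 10)
  expect_true(is.finite(pr2$s02) && pr2$s02 > 0)
  expect_error(estimate_prior(c(0, 0), df = 5), "zero")
})

test_that("the prior matches limma's fitFDist on heterogeneous variances", {
  skip_if_not_installed("limma")
  set.seed(4)
  s2 <- 0.05 * 4 / rchisq(500, 4) * rchisq(500, 20) / 20
  pr <- estimate_prior(s2, df = 20)
  fd <- limma::fitFDist(s2, df1 = 20)
  expect_equal(pr$d0, fd$df2, tolerance = 1e-6)
  expect_equal(pr$s02, fd$scale, tolerance = 1e-6)
})

test_that("moderated t collapses to OLS t at d0 = 0 and to the prior at d0 = Inf", {
  set.seed(5)
  fits <- data.frame(probe_id = paste0("p", 1:50),
                     coef = rnorm(50), u = 0.3,
                     s2 = rchisq(50, 10) / 10 * 0.2, df = 10)
  none <- moderated_t(fits, prior = list(d0 = 0, s02 = 1))
  t_ols <- fits$coef / (fits$u * sqrt(fits$s2))
  expect_equal(none$t, t_ols, tolerance = 1e-12)
  expect_equal(none$df_total, fits$df)

  full <- moderated_t(fits, prior = list(d0 = Inf, s02 = 0.2))
  expect_equal(full$s2_post, rep(0.2, 50))
  # probes with equal coef/u get equal moderated t under full shrinkage
  fits2 <- fits
  fits2$coef <- 1; fits2$u <- 0.5
  full2 <- moderated_t(fits2, prior = list(d0 = Inf, s02 = 0.2))
  expect_equal(length(unique(round(full2$t, 12))), 1)
})

test_that("posterior variance lies between s2 and s02 and shrinkage points the right way", {
  set.seed(6)
  for (i in 1:20) {
    fits <- data.frame(probe_id = paste0("p", 1:30),
                       coef = rnorm(30), u = runif(30, 0.1, 1),
                       s2 = rchisq(30, 8) / 8 * 0.1, df = 8)
    d0 <- runif(1, 0.5, 50)
    s02 <- runif(1, 0.01, 0.5)
    mt <- moderated_t(fits, prior = list(d0 = d0, s02 = s02))
    expect_true(all(mt$s2_post >= pmin(fits$s2, s02) - 1e-12))
    expect_true(all(mt$s2_post <= pmax(fits$s2, s02) + 1e-12))
    t_ols <- abs(fits$coef / (fits$u * sqrt(fits$s2)))
    smaller <- fits$s2 < s02
    expect_true(all(abs(mt$t)[smaller] <= t_ols[smaller] + 1e-12))
    expect_true(all(abs(mt$t)[!smaller] >= t_ols[!smaller] - 1e-12))
  }
})

test_that("the whole moderated pipeline agrees with limma on random data", {
  skip_if_not_installed("limma")
  set.seed(7)
  n <- 20; G <- 60
  x <- rnorm(n)
  m <- matrix(rnorm(G * n, sd = rep(runif(G, 0.2, 1), n)), nrow = G,
              dimnames = list(paste0("p", 1:G), paste0("S", 1:n)))
  design <- cbind(Intercept = 1, x = x)
  rownames(design) <- colnames(m)
  fits <- fit_probes(m, design, coef = "x")
  mt <- moderated_t(fits)
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(mt, "prior")$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mt, "prior")$s02, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(mt$t, lfit$t[, "x"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mt$p, lfit$p.value[, "x"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("bh_fdr matches hand computations and the step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("bh_fdr is order-preserving and never below the raw p-values", {
  set.seed(9)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  expect_true(all(q >= 0 & q <= 1))
})

test_that("run_dmp returns one row per probe, logs dropped samples, and is probe-order invariant", {
  ch <- small_cohort(30)
  ch$pheno$cortisol_baseline[1:4] <- NA
  m <- beta_to_m(ch$beta)
  expect_message(fit <- run_dmp(m, pheno = ch$pheno, preset = "dst",
                                phenotype = NULL), "dropped 4")
  expect_equal(nrow(fit), nrow(m))
  expect_equal(attr(fit, "n_dropped"), 4)
  expect_equal(attr(fit, "n_used"), 89)
  perm <- sample(nrow(m))
  fit_perm <- suppressMessages(
    run_dmp(m[perm, ], pheno = ch$pheno, preset = "dst", phenotype = NULL))
  reord <- fit_perm[match(fit$probe_id, fit_perm$probe_id), ]
  expect_equal(fit$t, reord$t, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$q, reord$q, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("run_dmp presets and contracts", {
  ch <- small_cohort(31)
  m <- beta_to_m(ch$beta)
  expect_error(run_dmp(m, pheno = ch$pheno, preset = "nope",
                       phenotype = NULL), "unknown preset")
  expect_error(run_dmp(m, phenotype = "not_a_column", pheno = ch$pheno),
               "lacks column")
  fit <- run_dmp(m, pheno = ch$pheno, preset = "tsh_t4", phenotype = NULL)
  expect_identical(attr(fit, "covariates"), c("hypersexuality", "il6"))
})

test_that("planted probes dominate the ranking under the stated power conditions", {
  hits <- 0L
  nseed <- 20
  for (i in seq_len(nseed)) {
    ch <- generate_cohort(cohort_config(
      planted_effects = c(AJ877169 = 1.0), noise_sd = 0.5, seed = 400 + i))
    m <- beta_to_m(ch$beta)
    fit <- suppressMessages(
      run_dmp(m, pheno = ch$pheno, preset = "dst", phenotype = NULL))
    planted <- c("cg07733851", "cg27122725")
    if (all(fit$p[match(planted, fit$probe_id)] < 0.05)) hits <- hits + 1L
  }
  expect_gte(hits / nseed, 0.95)
})
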