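test_that("probe averaging: identity, symmetry, idempotence", {
  m <- matrix(c(1, 2, 3, -1, -2, -3, 1, 2, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))
  expect_equal(average_probes(m, "a"), m["a", ])
  expect_equal(unname(average_probes(m, c("a", "b"))), c(0, 0, 0))
  expect_equal(average_probes(m, c("a", "c")), m["a", ])
  expect_error(average_probes(m, character(0)), "non-empty")
  expect_error(average_probes(m, "zz"), "not in matrix")
})

test_that("pearson_cor matches perfect lines and refuses constants", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 10)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("pearson r is invariant to affine transforms and recovers rho at n = 11", {
  set.seed(14)
  x <- rnorm(30); y <- x + rnorm(30)
  r0 <- pearson_cor(x, y)$r
  expect_equal(pearson_cor(3 * x - 2, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -2 * y + 5)$r, -r0, tolerance = 1e-12)
  # median sample r over seeds should sit near rho = 0.8 at cohort size 11
  rs <- vapply(1:200, function(s) {
    ec <- generate_expression_cohort(11, 0.8, seed = s)
    cor(ec$m, ec$expr)
  }, numeric(1))
  z <- atanh(median(rs))
  se <- 1 / sqrt(11 - 3)
  expect_lt(abs(z - atanh(0.8)), 2 * se / sqrt(200) * 10)  # tight around rho
})

test_that("robust fit is exact on a clean line and tracks OLS on clean Gaussian data", {
  x <- seq(-2, 2, length.out = 20)
  rb <- robust_fit(x, 2 * x + 1)
  expect_equal(rb$coefficient, 2, tolerance = 1e-6)
  expect_equal(rb$intercept, 1, tolerance = 1e-6)

  set.seed(15)
  x2 <- rnorm(100)
  y2 <- 1 + 0.5 * x2 + rnorm(100, sd = 0.3)
  rb2 <- robust_fit(x2, y2)
  ols <- coef(lm(y2 ~ x2))[2]
  # MM-estimate at ~90% efficiency: close to, not identical with, OLS
  expect_equal(rb2$coefficient, unname(ols), tolerance = 0.05)
  expect_error(robust_fit(1:4, 1:4), "n >= 5")
})

test_that("robust slope resists gross contamination that wrecks OLS", {
  set.seed(16)
  n <- 50
  x <- rnorm(n)
  y <- 2 * x + 1 + rnorm(n, sd = 0.5)
  out_idx <- order(x, decreasing = TRUE)[1:10]
  y[out_idx] <- y[out_idx] + 50    # 20% gross outliers at high leverage
  rb <- robust_fit(x, y)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(rb$coefficient - 2), 0.3)
  expect_gt(abs(ols - 2), 1)
})

test_that("robust t and p are invariant to standardizing x; slope rescales", {
  set.seed(17)
  x <- rnorm(40); y <- 1.5 * x + rnorm(40, sd = 0.4)
  raw <- robust_fit(x, y)
  xs <- (x - mean(x)) / sd(x)
  std <- robust_fit(xs, y)
  expect_equal(std$coefficient, raw$coefficient * sd(x), tolerance = 1e-4)
  expect_equal(std$t, raw$t, tolerance = 1e-4)
  expect_equal(std$p, raw$p, tolerance = 1e-4)
})

test_that("correlate_cohort averages multi-probe transcripts into one row", {
  set.seed(18)
  n <- 10
  ids <- sprintf("S%02d", 1:n)
  probes <- paste0("cg", 1:4)
  base <- rnorm(n)
  meth <- matrix(rep(base, each = 4), nrow = 4,
                 dimnames = list(probes, ids)) + rnorm(4 * n, sd = 0.1)
  expr <- matrix(base + rnorm(n, sd = 0.3), nrow = 1,
                 dimnames = list("CRHR2", ids))
  mapping <- data.frame(transcript = "EU012442", gene = "CRHR2",
                        probe_id = probes)
  res <- correlate_cohort(meth, expr, mapping, "test")
  expect_equal(nrow(res), 1)
  expect_equal(res$n_probes, 4)
  expect_gt(res$pearson_r, 0.5)
  expect_gt(res$robust_coef, 0)
})

test_that("generated rho = 0.9 cohorts recover a positive association nearly always", {
  pos <- vapply(1:40, function(s) {
    ec <- generate_expression_cohort(10, 0.9, seed = 600 + s)
    meth <- matrix(ec$m, nrow = 1, dimnames = list("cg1", names(ec$m)))
    expr <- matrix(ec$expr, nrow = 1, dimnames = list("G", names(ec$expr)))
    mp <- data.frame(transcript = "T", gene = "G", probe_id = "cg1")
    r <- correlate_cohort(meth, expr, mp, "sim")
    r$pearson_r > 0 && r$robust_coef > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})

test_that("null expression cohorts give roughly nominal Pearson false-positive rates", {
  ps <- vapply(1:300, function(s) {
    ec <- generate_expression_cohort(10, 0, seed = 700 + s)
    pearson_cor(ec$m, ec$expr)$p
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("shared-sample and missing-gene contracts hold", {
  meth <- matrix(rnorm(10), nrow = 1, dimnames = list("cg1", paste0("A", 1:10)))
  expr <- matrix(rnorm(10), nrow = 1, dimnames = list("G", paste0("B", 1:10)))
  mp <- data.frame(transcript = "T", gene = "G", probe_id = "cg1")
  expect_error(correlate_cohort(meth, expr, mp), "shared")
  expr2 <- matrix(rnorm(10), nrow = 1,
                  dimnames = list("OTHER", paste0("A", 1:10)))
  expect_error(correlate_cohort(meth, expr2, mp), "absent")
})
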