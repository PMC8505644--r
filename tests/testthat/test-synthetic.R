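test_that("default annotation mirrors the 76-probe panel structure", {
  ann <- default_annotation()
  expect_equal(length(unique(ann$probe_id)), 76)
  counts <- table(ann$transcript)
  expect_equal(unname(counts[["AJ877169"]]), 2)
  expect_equal(unname(counts[["EU012442"]]), 14)
  expect_true(all(c("cg07733851", "cg27122725") %in%
                    ann$probe_id[ann$transcript == "AJ877169"]))
  expect_true(all(abs(ann$tss_distance) <= 2000))
  expect_setequal(unique(ann$gene),
                  c("CRH", "CRHBP", "CRHR1", "CRHR2", "FKBP5", "NR3C1"))
})

test_that("same seed gives bit-identical cohorts; betas stay inside (0,1)", {
  a <- small_cohort(7)
  b <- small_cohort(7)
  expect_identical(a, b)
  expect_true(all(a$beta > 0 & a$beta < 1))
  expect_equal(dim(a$beta), c(76, 93))
  expect_equal(nrow(a$pheno), 93)
  expect_equal(sum(a$pheno$dst_ns), 20)
})

test_that("planted effect produces a positive group beta difference and converges as noise shrinks", {
  for (sd in c(0.3, 0.05)) {
    ch <- generate_cohort(cohort_config(
      planted_effects = c(AJ877169 = 1.0), noise_sd = sd, seed = 11))
    m <- beta_to_m(ch$beta)
    cases <- ch$pheno$sample_id[ch$pheno$dst_ns == 1]
    ctrls <- ch$pheno$sample_id[ch$pheno$dst_ns == 0]
    planted <- ch$truth$probe_effects$probe_id[
      ch$truth$probe_effects$true_effect > 0]
    dm <- rowMeans(m[planted, cases]) - rowMeans(m[planted, ctrls])
    db <- rowMeans(ch$beta[planted, cases]) - rowMeans(ch$beta[planted, ctrls])
    expect_true(all(db > 0))
    # empirical M-shift approaches the configured +1.0 as noise_sd -> 0
    expect_true(all(abs(dm - 1.0) < 6 * sd * sqrt(1 / 20 + 1 / 73) + 0.05))
  }
})

test_that("ground truth aligns with generated probes and planted transcripts", {
  ch <- generate_cohort(cohort_config(
    planted_effects = c(AJ877169 = 1.0, NM_004117 = -0.5), seed = 2))
  expect_identical(ch$truth$probe_effects$probe_id, rownames(ch$beta))
  expect_setequal(ch$truth$planted_transcripts, c("AJ877169", "NM_004117"))
  ann <- ch$annotation
  expect_equal(sum(ch$truth$probe_effects$true_effect == 1.0),
               sum(ann$transcript == "AJ877169"))
})

test_that("degenerate configs are rejected", {
  expect_error(cohort_config(n_cases = 1), "group sizes")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(hypersexuality_prev = c(1.2, 0.5)),
               "prevalence")
  expect_error(cohort_config(planted_effects = c(NOPE = 1)), "planted_effects")
})

test_that("missing-at-random injection hits continuous covariates only", {
  ch <- generate_cohort(cohort_config(missing_rate = 0.2, seed = 5))
  expect_gt(sum(is.na(ch$pheno$cortisol_baseline)), 0)
  expect_false(anyNA(ch$pheno$dst_ns))
  expect_false(anyNA(ch$beta))
})

test_that("expression cohort reproduces the requested correlation", {
  ec <- generate_expression_cohort(1000, rho = 0.99, seed = 3)
  expect_gt(cor(ec$m, ec$expr), 0.9)
  ec0 <- generate_expression_cohort(2000, rho = 0, seed = 4)
  # Fisher-z SE at n = 2000 is ~0.022; allow 4 SEs
  expect_lt(abs(cor(ec0$m, ec0$expr)), 0.09)
  expect_identical(generate_expression_cohort(10, 0.5, seed = 1),
                   generate_expression_cohort(10, 0.5, seed = 1))
  expect_error(generate_expression_cohort(2, 0.5), "n >= 3")
  expect_error(generate_expression_cohort(10, 1), "rho")
})

test_that("null cohort per-probe two-sample t rejects at about the nominal rate", {
  # Monte-Carlo over replicates: raw two-sample t on M-values of null data
  nrep <- 60
  hits <- 0L
  total <- 0L
  for (i in seq_len(nrep)) {
    ch <- small_cohort(1000 + i)
    m <- beta_to_m(ch$beta)
    g <- ch$pheno$dst_ns
    p <- apply(m, 1, function(y) stats::t.test(y[g == 1], y[g == 0])$p.value)
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  rate <- hits / total
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("write_cohort emits readable TSVs that round-trip", {
  dir <- withr::local_tempdir()
  ch <- small_cohort(9)
  write_cohort(ch, dir)
  beta_back <- read_matrix_tsv(file.path(dir, "beta.tsv"))
  expect_equal(unname(beta_back), unname(unclass(ch$beta)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rownames(beta_back), rownames(ch$beta))
})
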