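# Shared fixtures and independent oracles used across the suite.

# Write a small annotation TSV and return its path.
write_annotation_fixture <- function(lines = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  if (is.null(lines)) {
    lines <- c(
      "probe_id\tgene\ttranscript\ttss_distance",
      "cg0001\tNR3C1\tTX1\t-150",
      "cg0002\tNR3C1\tTX1\t1999",
      "cg0003\tFKBP5\tTX2\t300"
    )
  }
  writeLines(lines, path)
  path
}

# Independent Benjamini-Hochberg step-up oracle, written from the
# definition: sort, q_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Exact binomial tail by full enumeration of the probability mass.
binom_enum_oracle <- function(k, n, p0, sided = "two-sided") {
  mass <- vapply(0:n, function(x) {
    choose(n, x) * p0^x * (1 - p0)^(n - x)
  }, numeric(1))
  if (sided == "greater") {
    sum(mass[(k + 1):(n + 1)])
  } else {
    sum(mass[mass <= mass[k + 1] * (1 + 1e-7)])
  }
}

# Per-probe OLS via explicit normal equations (independent of lm.fit/QR).
ols_oracle <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  d <- nrow(X) - ncol(X)
  list(beta = drop(beta), s2 = sum(res^2) / d,
       u = sqrt(diag(xtx_inv)), df = d)
}

# Tiny null cohort config used in several property tests.
small_cohort <- function(seed, ...) {
  generate_cohort(cohort_config(seed = seed, ...))
}
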