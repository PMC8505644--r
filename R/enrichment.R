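# Per-transcript binomial enrichment of nominally significant CpGs.
#
# A single CpG rarely survives FDR correction in a small candidate panel,
# but a transcript whose probes are collectively enriched for nominally
# significant sites is informative. For each transcript, the number k of
# probes with raw p < alpha_nominal out of its n annotated probes is
# compared to Binomial(n, p0 = alpha_nominal) with an exact test, ignoring
# the direction of the methylation change; transcript-level p-values are
# Bonferroni-adjusted across all tested transcripts.

#' Exact binomial tail probability for probe enrichment
#'
#' Exact test of `k` successes in `n` trials against success probability
#' `p0`. `"greater"` is the upper tail `P(X >= k)`; `"two-sided"` sums
#' `P(X = x)` over all outcomes no more probable than the observed one
#' (the convention of [stats::binom.test()], which backs this function).
#'
#' @param k,n non-negative integers, `k <= n`, `n >= 1`.
#' @param p0 hypothesised success probability, in (0, 1). Default 0.05.
#' @param sided `"two-sided"` (default) or `"greater"`.
#' @return p-value.
#' @export
binomial_test <- function(k, n, p0 = 0.05,
                          sided = c("two-sided", "greater")) {
  sided <- match.arg(sided)
  assert_that(n >= 1 && k >= 0 && k <= n, "need 0 <= k <= n, n >= 1")
  assert_that(p0 > 0 && p0 < 1, "p0 must lie in (0, 1)")
  alt <- if (sided == "greater") "greater" else "two.sided"
  stats::binom.test(k, n, p = p0, alternative = alt)$p.value
}

#' Transcript-level enrichment of nominally significant probes
#'
#' Joins a moderated-fit table to the probe annotation, counts per
#' transcript the probes with raw `p < alpha_nominal` (direction ignored),
#' tests each count with [binomial_test()], and Bonferroni-adjusts across
#' the number of tested transcripts (those with at least one annotated
#' probe in the fit). Probes absent from the annotation are dropped with a
#' warning; a probe annotated to several transcripts counts in each.
#'
#' @param dmp moderated-fit data frame from [run_dmp()] (needs `probe_id`,
#'   `p`).
#' @param annotation probe annotation data frame.
#' @param alpha_nominal nominal significance threshold and binomial `p0`.
#'   Default 0.05.
#' @param sided sidedness passed to [binomial_test()].
#' @return data frame, one row per transcript: `transcript`, `gene`, `k`,
#'   `n`, `p_binomial`, `p_bonferroni`, `significant` (adjusted p < 0.05);
#'   Bonferroni multiplier attached as attribute `m_tests`.
#' @export
run_enrichment <- function(dmp, annotation, alpha_nominal = 0.05,
                           sided = c("two-sided", "greater")) {
  sided <- match.arg(sided)
  ann <- annotation[annotation$probe_id %in% dmp$probe_id, , drop = FALSE]
  n_unannotated <- sum(!dmp$probe_id %in% annotation$probe_id)
  if (n_unannotated > 0) {
    warning(sprintf("%d probe(s) in the fit have no annotation and are ignored",
                    n_unannotated), call. = FALSE)
  }
  if (nrow(ann) == 0) {
    stop_hpameth("no overlap between fitted probes and annotation")
  }
  sig_probes <- dmp$probe_id[dmp$p < alpha_nominal]
  transcripts <- unique(ann$transcript)
  m_tests <- length(transcripts)
  rows <- lapply(transcripts, function(tr) {
    sub <- ann[ann$transcript == tr, , drop = FALSE]
    n <- nrow(sub)
    k <- sum(sub$probe_id %in% sig_probes)
    p <- binomial_test(k, n, p0 = alpha_nominal, sided = sided)
    data.frame(transcript = tr, gene = sub$gene[1], k = k, n = n,
               p_binomial = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_binomial * m_tests)
  out$significant <- out$p_bonferroni < 0.05
  rownames(out) <- NULL
  attr(out, "m_tests") <- m_tests
  out
}
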