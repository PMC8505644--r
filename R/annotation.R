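# Probe-to-transcript annotation handling and TSS-window candidate selection.
#
# The analysis is restricted to CpG probes lying within a fixed window of a
# transcription start site (TSS) of one of the candidate HPA-axis genes.
# Distances are signed base pairs relative to the closest TSS (negative =
# upstream); strand resolution is assumed to be already encoded in the sign,
# so this module never inspects strand.

ANNOTATION_COLS <- c("probe_id", "gene", "transcript", "tss_distance")

#' Default HPA-axis candidate gene panel
#'
#' The six canonical HPA-axis genes: corticotropin-releasing hormone
#' (`CRH`), its binding protein (`CRHBP`), its two receptors (`CRHR1`,
#' `CRHR2`), the glucocorticoid-receptor co-chaperone `FKBP5`, and the
#' glucocorticoid receptor itself (`NR3C1`).
#'
#' @param genes character vector of gene symbols.
#' @param window_bp positive integer, half-width of the TSS window in base
#'   pairs. Probes with `|tss_distance| <= window_bp` are retained.
#' @return object of class `candidate_panel`: list with `genes`, `window_bp`.
#' @export
candidate_panel <- function(genes = c("CRH", "CRHBP", "CRHR1", "CRHR2",
                                      "FKBP5", "NR3C1"),
                            window_bp = 2000L) {
  assert_that(length(genes) > 0, "candidate panel must contain >= 1 gene")
  assert_that(is.numeric(window_bp) && length(window_bp) == 1 &&
                is.finite(window_bp) && window_bp > 0,
              "window_bp must be a single positive number")
  structure(list(genes = as.character(genes),
                 window_bp = as.numeric(window_bp)),
            class = "candidate_panel")
}

#' Load a probe annotation table
#'
#' Reads a TSV/CSV with columns `probe_id`, `gene`, `transcript`,
#' `tss_distance` (signed bp to the closest TSS). Rows whose distance cannot
#' be parsed as a finite number are dropped; their row numbers are reported
#' in a warning and attached as attribute `rejected_rows`.
#'
#' @param path path to the annotation file.
#' @return data frame with the four annotation columns, one row per
#'   (probe, transcript) pair.
#' @export
load_annotation <- function(path) {
  df <- read_delim_auto(path)
  missing_cols <- setdiff(ANNOTATION_COLS, colnames(df))
  if (length(missing_cols) > 0) {
    stop_hpameth(sprintf("annotation is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  df <- df[, ANNOTATION_COLS]
  dist <- suppressWarnings(as.numeric(df$tss_distance))
  bad <- which(!is.finite(dist))
  if (length(bad) > 0) {
    warning(sprintf("rejected %d annotation row(s) with unparseable tss_distance: row(s) %s",
                    length(bad), paste(bad, collapse = ", ")), call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    dist <- dist[-bad]
  }
  df$tss_distance <- dist
  df$probe_id <- as.character(df$probe_id)
  df$gene <- as.character(df$gene)
  df$transcript <- as.character(df$transcript)
  if (any(!nzchar(df$probe_id))) stop_hpameth("empty probe_id in annotation")
  key <- paste(df$probe_id, df$transcript, sep = "\r")
  if (anyDuplicated(key)) {
    stop_hpameth("duplicate (probe_id, transcript) rows in annotation")
  }
  rownames(df) <- NULL
  attr(df, "rejected_rows") <- bad
  df
}

#' Select candidate probes in the TSS window of panel genes
#'
#' Keeps exactly the annotation rows whose gene is in the panel and whose
#' absolute TSS distance is at most the panel window (inclusive at the
#' boundary). Order-preserving and idempotent. A probe annotated to several
#' transcripts is kept once per transcript, so downstream per-transcript
#' probe counts include it in each.
#'
#' @param annotation data frame as from [load_annotation()].
#' @param panel a [candidate_panel()].
#' @return subset of `annotation` rows.
#' @export
select_candidate_probes <- function(annotation, panel = candidate_panel()) {
  assert_that(inherits(panel, "candidate_panel"),
              "panel must be a candidate_panel")
  assert_that(nrow(annotation) > 0, "annotation is empty")
  keep <- annotation$gene %in% panel$genes &
    abs(annotation$tss_distance) <= panel$window_bp
  out <- annotation[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no probes match the candidate panel within the TSS window",
            call. = FALSE)
  }
  out
}
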