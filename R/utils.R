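#' @keywords internal
"_PACKAGE"

# Run an expression under a temporary RNG seed, restoring the caller's
# random-number stream afterwards. Used wherever an algorithm needs internal
# randomness (e.g. the S-estimate subsampling in robust regression) without
# perturbing user-level reproducibility.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stop_hpameth <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_hpameth(msg)
  invisible(TRUE)
}

#' Write a data frame as tab-separated values
#'
#' Plain TSV with a header row and no quoting/row names; the on-disk format
#' used by every pipeline stage.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_hpameth(sprintf("file not found: '%s'", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' Write a numeric matrix with row identifiers as TSV
#'
#' @param m numeric matrix with rownames (features) and colnames (samples).
#' @param path output file path.
#' @param id_col name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv_table(df, path)
}

#' Read a feature-by-sample numeric matrix from TSV/CSV
#'
#' First column is taken as feature identifiers, remaining columns as samples.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_delim_auto(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
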