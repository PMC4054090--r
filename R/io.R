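# Readers and writers for the plain-text interchange formats used around
# the pipeline.

.BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a BLAST tabular hit file
#'
#' Standard 12-column outfmt-6 dialect, optionally with a 13th free-text
#' description column.
#'
#' @param file Path to a tab-separated hit table (no header).
#' @return `data.frame` with the standard column names (plus
#'   `description` when a 13th column is present).
#' @export
read_blast_tabular <- function(file) {
  tab <- utils::read.table(file, sep = "\t", quote = "", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 12L)
    stop("expected >= 12 tab-separated columns, got ", ncol(tab), call. = FALSE)
  names(tab)[1:12] <- .BLAST_COLS
  if (ncol(tab) >= 13L) names(tab)[13] <- "description"
  tab[, seq_len(min(ncol(tab), 13L)), drop = FALSE]
}

#' @rdname read_blast_tabular
#' @param hits Hit `data.frame` with at least the 12 standard columns.
#' @export
write_blast_tabular <- function(hits, file) {
  cols <- c(.BLAST_COLS, intersect("description", names(hits)))
  utils::write.table(hits[, cols, drop = FALSE], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write/read a simple tab-separated table with header
#'
#' @param x `data.frame` (list columns are collapsed with commas).
#' @param file Path.
#' @export
write_tsv <- function(x, file) {
  x <- as.data.frame(x)
  for (cn in names(x))
    if (is.list(x[[cn]]))
      x[[cn]] <- vapply(x[[cn]], function(v) paste(v, collapse = ","), character(1))
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", quote = "", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}
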