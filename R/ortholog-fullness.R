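# Reciprocal-best-hit orthologue pairing and alignment-fraction
# full-length calling.

# best hit per query of a hit table: lowest e-value, ties by descending
# bitscore then subject id
.best_per_query <- function(tab) {
  if (nrow(tab) == 0L) return(tab)
  ord <- order(tab$qseqid, tab$evalue, -tab$bitscore, tab$sseqid)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$qseqid), , drop = FALSE]
  tab
}

#' Reciprocal best hit orthologue pairs
#'
#' A pair (query, subject) is emitted iff the subject is the query's best
#' hit in `query_hits` and the query is the subject's best hit in
#' `subject_hits` (best = lowest e-value, ties broken by descending
#' bitscore then subject id).  With `reciprocal = FALSE` only the
#' query-side best mapping is required.
#'
#' @param query_hits,subject_hits BLAST-tabular-style `data.frame`s with
#'   `qseqid`, `sseqid`, `evalue`, `bitscore` and (for alignment length)
#'   `sstart`, `send` or `length`.
#' @param reciprocal Require reciprocity (default `TRUE`).
#' @return `data.frame` with `query_id`, `subject_id`, `evalue`,
#'   `bitscore`, `align_length` (subject coverage of the query-side hit).
#' @export
reciprocal_best_pairs <- function(query_hits, subject_hits,
                                  reciprocal = TRUE) {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      align_length = integer(), stringsAsFactors = FALSE)
  if (nrow(query_hits) == 0L) return(empty)
  bq <- .best_per_query(query_hits)
  if (reciprocal) {
    bs <- .best_per_query(subject_hits)
    back <- stats::setNames(bs$sseqid, bs$qseqid)
    keep <- !is.na(back[bq$sseqid]) & back[bq$sseqid] == bq$qseqid
    bq <- bq[keep, , drop = FALSE]
  }
  if (nrow(bq) == 0L) return(empty)
  alen <- if (all(c("sstart", "send") %in% names(bq))) {
    abs(bq$send - bq$sstart) + 1L
  } else bq$length
  out <- data.frame(query_id = bq$qseqid, subject_id = bq$sseqid,
                    evalue = bq$evalue, bitscore = bq$bitscore,
                    align_length = as.integer(alen),
                    stringsAsFactors = FALSE)
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call full-length transcripts from orthologue alignment fractions
#'
#' A transcript is full length when its alignment covers strictly more
#' than `full_length_frac` of the orthologue (subject) sequence.
#' Fractions above 1 are permitted: de novo transcripts are frequently
#' somewhat longer than their orthologues.
#'
#' @param pairs `data.frame` from [reciprocal_best_pairs()].
#' @param subject_lengths `data.frame` with `subject_id` and `length`
#'   (residues), or a named numeric vector.
#' @param full_length_frac Full-length threshold (strict `>`), default
#'   0.75.
#' @return `data.frame` of pairs with added `subject_length`,
#'   `align_fraction`, `full_length`.  Rows with missing or nonpositive
#'   subject length are excluded and returned in the `rejected`
#'   attribute.  A `summary` attribute carries `n_pairs`, `n_full` and
#'   `pct_full`.
#' @export
call_full_length <- function(pairs, subject_lengths, full_length_frac = 0.75) {
  if (is.data.frame(subject_lengths))
    subject_lengths <- stats::setNames(subject_lengths$length,
                                       subject_lengths$subject_id)
  out <- pairs
  out$subject_length <- as.numeric(subject_lengths[out$subject_id])
  bad <- is.na(out$subject_length) | out$subject_length <= 0
  rejected <- out[bad, , drop = FALSE]
  if (nrow(rejected) > 0L)
    warning(nrow(rejected), " pair(s) rejected: missing or nonpositive subject length")
  out <- out[!bad, , drop = FALSE]
  out$align_fraction <- out$align_length / out$subject_length
  out$full_length <- out$align_fraction > full_length_frac
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "summary") <- list(
    n_pairs = nrow(out), n_full = sum(out$full_length),
    pct_full = if (nrow(out) > 0L) 100 * mean(out$full_length) else NA_real_)
  out
}
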