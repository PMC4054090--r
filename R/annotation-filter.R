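# E-value thresholding, keyword quality flagging, best-GO-hit selection
# and annotation-rate-versus-length curves.

#' Filter homology hits by e-value and flag weak description lines
#'
#' Retains hits with `evalue <= cutoff` (inclusive) and flags hits whose
#' description contains any configured keyword (case-insensitive substring
#' by default, whole-word optionally).  Malformed rows (missing or negative
#' e-value) are dropped, counted and reported via the `n_malformed`
#' attribute, not as an error.
#'
#' @param hits `data.frame` with at least `evalue` and `description`
#'   columns (see [as_annotation_hits()]).
#' @param cutoff E-value cutoff (> 0), default `1e-15`.
#' @param keywords Character vector of low-quality keywords.
#' @param word_boundary Require whole-word keyword matches (default
#'   `FALSE`: plain substring).
#' @return Filtered `data.frame` with an added logical `low_quality`
#'   column and attribute `n_malformed`.
#' @export
filter_hits <- function(hits, cutoff = 1e-15,
                        keywords = c("mRNA", "cDNA", "clone", "genomic"),
                        word_boundary = FALSE) {
  .stopifnot_scalar_number(cutoff, "cutoff")
  if (cutoff <= 0) stop("'cutoff' must be > 0", call. = FALSE)
  bad <- is.na(hits$evalue) | hits$evalue < 0
  n_malformed <- sum(bad)
  if (n_malformed > 0L)
    message(n_malformed, " malformed hit row(s) dropped")
  hits <- hits[!bad, , drop = FALSE]
  out <- hits[hits$evalue <= cutoff, , drop = FALSE]
  desc <- tolower(out$description)
  lq <- rep(FALSE, nrow(out))
  for (kw in keywords) {
    pat <- if (word_boundary) sprintf("\\b%s\\b", tolower(kw)) else tolower(kw)
    lq <- lq | grepl(pat, desc, fixed = !word_boundary)
  }
  out$low_quality <- lq
  rownames(out) <- NULL
  attr(out, "n_malformed") <- n_malformed
  out
}

# canonical hit rating: ascending e-value, descending bitscore, then
# subject id for a deterministic order
.rate_order <- function(h) order(h$evalue, -h$bitscore, h$subject_id)

#' Select top hits and the best GO-bearing functional assignment
#'
#' Per (query, taxon, database) the top `k` hits by ascending e-value
#' (ties: descending bitscore, then subject id) are retained.  The
#' functional assignment per (query, taxon) is the best-rated hit whose
#' subject carries at least one GO term in `go_map`, applying the stricter
#' functional e-value cutoff (default `1e-20`).
#'
#' @param hits Filtered hits from [filter_hits()] with `query_id`,
#'   `taxon`, `database`, `subject_id`, `evalue`, `bitscore`.
#' @param go_map `data.frame` with `subject_id` and `go_terms`
#'   (semicolon-separated); subjects absent from the map simply carry no
#'   GO annotation.
#' @param k Hits retained per (query, taxon, database), default 3.
#' @param functional_cutoff E-value cutoff for functional assignment,
#'   default `1e-20`.
#' @return List with `top_hits` (retained hits) and `assignments`
#'   (`data.frame` of `query_id`, `taxon`, `subject_id`, `evalue`,
#'   `go_terms`); queries with no GO-bearing hit are annotated but
#'   functionally unassigned (absent from `assignments`).
#' @export
select_best_annotation <- function(hits, go_map = NULL, k = 3L,
                                   functional_cutoff = 1e-20) {
  .stopifnot_scalar_number(k, "k", lower = 1)
  if (nrow(hits) == 0L)
    return(list(top_hits = hits,
                assignments = data.frame(query_id = character(),
                                         taxon = character(),
                                         subject_id = character(),
                                         evalue = numeric(),
                                         go_terms = character(),
                                         stringsAsFactors = FALSE)))
  grp <- interaction(hits$query_id, hits$taxon, hits$database, drop = TRUE)
  top <- do.call(rbind, lapply(split(hits, grp), function(h) {
    utils::head(h[.rate_order(h), , drop = FALSE], k)
  }))
  rownames(top) <- NULL

  go_subjects <- character(0)
  go_terms <- character(0)
  if (!is.null(go_map) && nrow(go_map) > 0L) {
    has_go <- !is.na(go_map$go_terms) & nzchar(go_map$go_terms)
    go_subjects <- go_map$subject_id[has_go]
    go_terms <- go_map$go_terms[has_go]
  }
  func <- hits[hits$evalue <= functional_cutoff &
                 hits$subject_id %in% go_subjects, , drop = FALSE]
  assignments <- do.call(rbind, lapply(
    split(func, interaction(func$query_id, func$taxon, drop = TRUE)),
    function(h) utils::head(h[.rate_order(h), , drop = FALSE], 1L)))
  if (is.null(assignments)) {
    assignments <- data.frame(query_id = character(), taxon = character(),
                              subject_id = character(), evalue = numeric(),
                              go_terms = character(), stringsAsFactors = FALSE)
  } else {
    assignments <- assignments[, c("query_id", "taxon", "subject_id", "evalue")]
    assignments$go_terms <- go_terms[match(assignments$subject_id, go_subjects)]
    assignments <- assignments[order(assignments$query_id, assignments$taxon), ,
                               drop = FALSE]
    rownames(assignments) <- NULL
  }
  list(top_hits = top, assignments = assignments)
}

#' Annotation rate as a function of transcript length
#'
#' For each e-value cutoff a transcript counts as annotated when at least
#' one hit survives that cutoff.  Rates are computed per 50 bp length bin
#' (or cumulatively over the tail of transcripts at least as long as the
#' bin start, with `cumulative = TRUE`).  `L50` is the smallest bin start,
#' scanning ascending over nonempty bins, at which the rate reaches 0.5;
#' the rate is not required to stay above 0.5 afterwards.  The annotation
#' rate among transcripts of at least `length_filter` nt is also reported.
#'
#' @param transcripts Transcript sequences or a named integer vector of
#'   lengths (names = transcript ids).
#' @param hits Hit `data.frame` with `query_id` and `evalue` (pre- or
#'   post-[filter_hits()]).
#' @param cutoffs Numeric vector of e-value cutoffs (nonempty).
#' @param bin_width Length bin width in bp, default 50.
#' @param length_filter Length filter in bp for the summary rate,
#'   default 400.
#' @param cumulative Use tail-cumulative rates instead of per-bin rates.
#' @return List with `curves` (`data.frame`: `cutoff`, `bin_start`,
#'   `bin_end`, `n_total`, `n_annotated`, `rate`) and `summary`
#'   (`data.frame`: `cutoff`, `l50`, `rate_ge_filter`, `n_ge_filter`).
#'   `l50` is `NA` when no bin reaches 0.5.
#' @export
annotation_rate_curve <- function(transcripts, hits, cutoffs,
                                  bin_width = 50L, length_filter = 400L,
                                  cumulative = FALSE) {
  if (length(cutoffs) == 0L) stop("'cutoffs' must be nonempty", call. = FALSE)
  if (is.numeric(transcripts)) {
    lens <- transcripts
    if (is.null(names(lens))) stop("length vector must be named", call. = FALSE)
  } else {
    set <- .as_dna_set(transcripts)
    lens <- stats::setNames(Biostrings::width(set), names(set))
  }
  if (length(lens) == 0L) stop("empty transcript set", call. = FALSE)
  b <- as.integer(lens %/% bin_width) * as.integer(bin_width)
  bins <- sort(unique(b))

  curves <- list(); summaries <- list()
  for (cutoff in cutoffs) {
    annotated_ids <- unique(hits$query_id[!is.na(hits$evalue) &
                                            hits$evalue <= cutoff])
    is_ann <- names(lens) %in% annotated_ids
    per_bin <- data.frame(cutoff = cutoff, bin_start = bins,
                          bin_end = bins + as.integer(bin_width))
    if (cumulative) {
      per_bin$n_total <- vapply(bins, function(x) sum(lens >= x), integer(1))
      per_bin$n_annotated <- vapply(bins, function(x)
        sum(is_ann[lens >= x]), integer(1))
    } else {
      per_bin$n_total <- vapply(bins, function(x) sum(b == x), integer(1))
      per_bin$n_annotated <- vapply(bins, function(x)
        sum(is_ann[b == x]), integer(1))
    }
    per_bin$rate <- per_bin$n_annotated / per_bin$n_total
    reach <- which(per_bin$rate >= 0.5)
    l50 <- if (length(reach) == 0L) NA_integer_ else per_bin$bin_start[reach[1L]]
    ge <- lens >= length_filter
    summaries[[length(summaries) + 1L]] <- data.frame(
      cutoff = cutoff, l50 = l50,
      rate_ge_filter = if (any(ge)) mean(is_ann[ge]) else NA_real_,
      n_ge_filter = sum(ge))
    curves[[length(curves) + 1L]] <- per_bin
  }
  list(curves = do.call(rbind, curves), summary = do.call(rbind, summaries))
}
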