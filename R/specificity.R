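# Species-specificity classification of peptide-verified transcripts and
# similarity clustering of candidate novel proteins.

#' Classify transcripts by database specificity of their surviving hits
#'
#' `no_hit`: zero surviving hits anywhere; `urodele_only`: all surviving
#' hits come from databases designated urodele-only; otherwise
#' `annotated`.  A transcript is a novelty candidate when it is peptide
#' verified and its class is `no_hit` or `urodele_only`.
#'
#' @param decisions Surviving hits per transcript (e.g. `top_hits` from
#'   [select_best_annotation()] or the output of [filter_hits()]), with
#'   `query_id` and `database` columns.
#' @param transcript_ids All transcript ids to classify (transcripts
#'   without hits must still receive a call).
#' @param verified_ids Transcript ids with peptide support (e.g. from
#'   [summarize_validation()]'s `per_transcript`, at the chosen minimum
#'   peptide count).
#' @param urodele_dbs Database names designated urodele-only.
#' @param known_dbs Optional full list of legal database names; a hit from
#'   a database outside it is an error.  Default `NULL` accepts any.
#' @return `data.frame` with `transcript_id`, `class`, `peptide_verified`,
#'   `candidate`.
#' @export
classify_specificity <- function(decisions, transcript_ids, verified_ids,
                                 urodele_dbs = "est_urodele",
                                 known_dbs = NULL) {
  if (!is.null(known_dbs)) {
    unknown <- setdiff(unique(decisions$database), known_dbs)
    if (length(unknown) > 0L)
      stop("unknown database name(s) in hits: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  hit_dbs <- split(decisions$database, decisions$query_id)
  cls <- vapply(transcript_ids, function(id) {
    dbs <- hit_dbs[[id]]
    if (is.null(dbs) || length(dbs) == 0L) "no_hit"
    else if (all(dbs %in% urodele_dbs)) "urodele_only"
    else "annotated"
  }, character(1))
  verified <- transcript_ids %in% verified_ids
  data.frame(transcript_id = transcript_ids,
             class = unname(cls),
             peptide_verified = verified,
             candidate = verified & cls %in% c("no_hit", "urodele_only"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# identity and shorter-sequence coverage of the best local protein
# alignment (BLOSUM62)
.protein_pair_stats <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncols <- length(pa)
  if (ncols == 0L) return(c(identity = 0, coverage = 0))
  ident <- sum(pa == sa & pa != "-") / ncols
  shorter <- min(length(a), length(b))
  span <- min(Biostrings::end(Biostrings::pattern(aln)) -
                Biostrings::start(Biostrings::pattern(aln)) + 1L,
              Biostrings::end(Biostrings::subject(aln)) -
                Biostrings::start(Biostrings::subject(aln)) + 1L)
  c(identity = ident, coverage = span / shorter)
}

#' Cluster candidate novel proteins by pairwise similarity
#'
#' Single-linkage clusters where two proteins are linked when their best
#' local alignment reaches `min_identity` over the aligned region and
#' covers at least `min_coverage` of the shorter sequence.  Clusters of
#' size >= 2 are reported as putative families.
#'
#' @param proteins [Biostrings::AAStringSet] or named character vector.
#' @param min_identity Minimum aligned-region identity, default 0.35.
#' @param min_coverage Minimum coverage of the shorter sequence, default
#'   0.6.
#' @return `data.frame` with `cluster_id`, `member_id`, `size`,
#'   `is_family` (`size >= 2`).
#' @export
cluster_novel_proteins <- function(proteins, min_identity = 0.35,
                                   min_coverage = 0.6) {
  aa <- .as_aa_set(proteins)
  n <- length(aa)
  ids <- names(aa)
  edges <- NULL
  if (n >= 2L) {
    ord <- order(ids)
    pairs <- t(utils::combn(n, 2L))
    linked <- apply(pairs, 1L, function(p) {
      i <- p[1]; j <- p[2]
      if (match(i, ord) > match(j, ord)) { tmp <- i; i <- j; j <- tmp }
      st <- .protein_pair_stats(aa[[i]], aa[[j]])
      st["identity"] >= min_identity && st["coverage"] >= min_coverage
    })
    edges <- pairs[linked, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  members <- split(seq_len(n), comp)
  cl_order <- order(vapply(members, function(v) min(ids[v]), character(1)))
  out <- do.call(rbind, lapply(seq_along(cl_order), function(ci) {
    v <- members[[cl_order[ci]]]
    v <- v[order(ids[v])]
    data.frame(cluster_id = sprintf("FAM%04d", ci),
               member_id = ids[v], size = length(v),
               is_family = length(v) >= 2L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
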