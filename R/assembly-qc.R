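# Assembly summary statistics and greedy redundancy clustering of
# pre-assembled contig pools.

#' N50 of a transcript set
#'
#' Smallest length N such that transcripts of length >= N together contain
#' at least half of all assembled bases (sort descending, accumulate; the
#' accumulating transcript's own length counts before the comparison).
#'
#' @param x Transcript sequences ([Biostrings::DNAStringSet], character
#'   vector) or a numeric vector of lengths.
#' @return Integer N50 in nt.
#' @export
compute_n50 <- function(x) {
  lens <- if (is.numeric(x)) as.numeric(x) else Biostrings::width(.as_dna_set(x, "x"))
  if (length(lens) == 0L) stop("cannot compute N50 of an empty set", call. = FALSE)
  if (any(lens <= 0)) stop("all lengths must be positive", call. = FALSE)
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  lens[which(cumsum(lens) >= half)[1L]]
}

#' Transcript length histogram
#'
#' Half-open bins `[k*w, (k+1)*w)`.
#'
#' @inheritParams compute_n50
#' @param bin_width Bin width in nt (> 0), default 50.
#' @return `data.frame` with `bin_start`, `bin_end`, `count`; only
#'   nonempty bins are reported, counts sum to the number of transcripts.
#' @export
length_histogram <- function(x, bin_width = 50L) {
  .stopifnot_scalar_number(bin_width, "bin_width", lower = 1)
  lens <- if (is.numeric(x)) x else Biostrings::width(.as_dna_set(x, "x"))
  if (length(lens) == 0L)
    return(data.frame(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  b <- as.integer(lens %/% bin_width) * as.integer(bin_width)
  tab <- table(b)
  data.frame(bin_start = as.integer(names(tab)),
             bin_end = as.integer(names(tab)) + as.integer(bin_width),
             count = as.integer(tab))
}

#' Assembly summary statistics
#'
#' @inheritParams compute_n50
#' @return List with `n_transcripts`, `n50`, `n_ge_400`, `n_ge_500`,
#'   `n_ge_1000`, `total_bases`.
#' @export
assembly_stats <- function(x) {
  lens <- if (is.numeric(x)) x else Biostrings::width(.as_dna_set(x, "x"))
  if (length(lens) == 0L) stop("empty transcript set", call. = FALSE)
  list(n_transcripts = length(lens),
       n50 = compute_n50(lens),
       n_ge_400 = sum(lens >= 400),
       n_ge_500 = sum(lens >= 500),
       n_ge_1000 = sum(lens >= 1000),
       total_bases = sum(lens))
}

# Identity and overhang of the best local alignment between two sequences,
# trying the second sequence on both strands.  Identity counts a column as
# a match only when both characters are equal and unambiguous (A/C/G/T),
# over all aligned columns including gaps.  The overhang constraint applies
# to every unaligned terminal stretch of either sequence, so a containment
# with long flanks on the containing sequence does not link.
.pair_link <- function(a, b, min_identity, max_overhang) {
  for (flip in c(FALSE, TRUE)) {
    bb <- if (flip) Biostrings::reverseComplement(b) else b
    aln <- Biostrings::pairwiseAlignment(a, bb, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ncol_aln <- length(pa)
    if (ncol_aln == 0L) next
    matches <- sum(pa == sa & pa %in% .DNA4)
    ident <- matches / ncol_aln

    la <- length(a); lb <- length(bb)
    over <- c(Biostrings::start(Biostrings::pattern(aln)) - 1L,
              la - Biostrings::end(Biostrings::pattern(aln)),
              Biostrings::start(Biostrings::subject(aln)) - 1L,
              lb - Biostrings::end(Biostrings::subject(aln)))
    if (ident >= min_identity && all(over <= max_overhang)) return(TRUE)
  }
  FALSE
}

# shared-kmer prefilter: candidate pairs are those sharing at least one
# canonical k-mer (lexicographic min of the k-mer and its reverse
# complement), so strand flips do not change candidacy
.kmer_candidate_pairs <- function(set, k) {
  n <- length(set)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  kmers <- lapply(seq_len(n), function(i) {
    s <- set[[i]]
    if (length(s) < k) return(character(0))
    fwd <- as.character(Biostrings::Views(s, start = seq_len(length(s) - k + 1L), width = k))
    rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
    unique(pmin(fwd, rev))
  })
  idx <- rep(seq_len(n), lengths(kmers))
  by_kmer <- split(idx, unlist(kmers))
  pairs <- unique(do.call(rbind, lapply(by_kmer, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2L) return(NULL)
    t(utils::combn(v, 2L))
  })))
  if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs
}

#' Greedy redundancy clustering of transcripts
#'
#' Single-linkage clustering where two transcripts are linked when a local
#' alignment (on either strand) reaches at least `min_identity` over the
#' aligned region while leaving at most `max_overhang` unaligned bases at
#' every sequence end, so redundant sequences must overlap near-globally.
#' A shared-k-mer prefilter restricts which pairs are aligned.  Ambiguous
#' bases never count as matches.
#'
#' The cluster representative is the longest member (ties: lexicographically
#' smallest id).  Cluster ids are assigned in order of representative id, so
#' the output is invariant under permutations of the input.
#'
#' @param transcripts [Biostrings::DNAStringSet] or named character vector.
#' @param min_identity Minimum aligned-region identity, default 0.90.
#' @param max_overhang Maximum unmatched overhang per end of the shorter
#'   sequence, in nt; default 30.
#' @param kmer Prefilter k-mer size, default 16.
#' @return `data.frame` with `cluster_id`, `member_id`,
#'   `is_representative`; rows partition the input ids.
#' @export
greedy_redundancy_cluster <- function(transcripts, min_identity = 0.90,
                                      max_overhang = 30L, kmer = 16L) {
  set <- .as_dna_set(transcripts)
  if (min_identity <= 0 || min_identity > 1)
    stop("'min_identity' must be in (0, 1]", call. = FALSE)
  .stopifnot_scalar_number(max_overhang, "max_overhang", lower = 0)
  n <- length(set)
  ids <- names(set)

  # evaluate each candidate pair in canonical id order so results do not
  # depend on input order
  ord <- order(ids)
  pairs <- .kmer_candidate_pairs(set, as.integer(kmer))
  edges <- NULL
  if (nrow(pairs) > 0L) {
    rank_of <- match(seq_len(n), ord)
    linked <- apply(pairs, 1L, function(p) {
      i <- p[1]; j <- p[2]
      if (rank_of[i] > rank_of[j]) { tmp <- i; i <- j; j <- tmp }
      .pair_link(set[[i]], set[[j]], min_identity, max_overhang)
    })
    edges <- pairs[linked, , drop = FALSE]
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  members <- split(seq_len(n), comp)
  lens <- Biostrings::width(set)
  reps <- vapply(members, function(v) {
    v[order(-lens[v], ids[v])][1L]
  }, integer(1))
  cl_order <- order(ids[reps])
  out <- do.call(rbind, lapply(seq_along(cl_order), function(ci) {
    v <- members[[cl_order[ci]]]
    rep_i <- reps[[cl_order[ci]]]
    v <- v[order(ids[v])]
    data.frame(cluster_id = sprintf("CL%05d", ci),
               member_id = ids[v],
               is_representative = v == rep_i,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Representative sequences of a clustering
#'
#' @param clusters `data.frame` from [greedy_redundancy_cluster()].
#' @param transcripts The sequences that were clustered.
#' @return [Biostrings::DNAStringSet] of representatives.
#' @export
cluster_representatives <- function(clusters, transcripts) {
  set <- .as_dna_set(transcripts)
  set[clusters$member_id[clusters$is_representative]]
}
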