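# Peptide-to-transcript matching on six-frame translations, coding
# validation, frameshift detection and target-decoy FDR.

.collapse_il <- function(x) chartr("I", "L", x)

#' Match identified peptides to six-frame ORF translations
#'
#' Exact substring search of peptide sequences against the amino-acid
#' sequences of a stop-to-stop ORF search database (see
#' [build_search_db()]).  Isoleucine and leucine are treated as equivalent
#' by default since their masses are indistinguishable in MS.  Peptides
#' containing `X`, and database slices containing `X`, never match.  Every
#' occurrence is reported with amino-acid coordinates on the frame's
#' translation and mapped forward-strand nucleotide coordinates.
#'
#' @param peptides Character vector of uppercase peptide sequences.
#' @param search_db ORF `data.frame` from [build_search_db()] (or
#'   [extract_orfs()] output).
#' @param il_equivalent Treat I and L as equivalent (default `TRUE`).
#' @param decoy Mark all reported hits as decoy hits (used when
#'   `search_db` is a decoy database; nt coordinates are then `NA`).
#' @return `data.frame` with `peptide`, `transcript_id`, `frame`,
#'   `aa_start`, `aa_end` (0-based half-open on the frame translation),
#'   `nt_start`, `nt_end` (0-based half-open, forward strand), `is_decoy`.
#' @export
match_peptides <- function(peptides, search_db, il_equivalent = TRUE,
                           decoy = FALSE) {
  peptides <- unique(as.character(peptides))
  if (length(peptides) > 0L) {
    ok <- grepl(sprintf("^[%s]+$", paste(c(.AA20, "X"), collapse = "")), peptides)
    if (!all(ok))
      stop("invalid residue characters in peptide(s): ",
           paste(utils::head(peptides[!ok], 5), collapse = ", "), call. = FALSE)
  }
  empty <- data.frame(peptide = character(), transcript_id = character(),
                      frame = integer(), aa_start = integer(),
                      aa_end = integer(), nt_start = integer(),
                      nt_end = integer(), is_decoy = logical(),
                      stringsAsFactors = FALSE)
  if (length(peptides) == 0L || nrow(search_db) == 0L) return(empty)

  searchable <- peptides[!grepl("X", peptides, fixed = TRUE)]
  if (length(searchable) == 0L) return(empty)

  db_seq <- search_db$aa_sequence
  if (il_equivalent) {
    searchable_q <- .collapse_il(searchable)
    db_seq <- .collapse_il(db_seq)
  } else searchable_q <- searchable

  # concatenate entries with a separator and search once per peptide
  sep <- "#"
  concat <- paste(db_seq, collapse = sep)
  ent_start <- cumsum(c(0L, nchar(db_seq) + 1L))[seq_along(db_seq)] # 0-based
  rows <- vector("list", length(searchable))
  for (p in seq_along(searchable)) {
    # zero-width lookahead so overlapping occurrences are all reported
    m <- gregexpr(sprintf("(?=%s)", searchable_q[p]), concat, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    pos0 <- as.integer(m) - 1L                     # 0-based global offsets
    ent <- findInterval(pos0, ent_start)           # entry index (1-based)
    off <- pos0 - ent_start[ent]                   # offset within entry
    plen <- nchar(searchable[p])
    e <- search_db[ent, , drop = FALSE]
    a0 <- e$aa_start + off
    a1 <- a0 + plen
    f <- abs(e$frame)
    L <- e$transcript_length
    nt0 <- ifelse(e$frame > 0, (f - 1L) + 3L * a0, L - ((f - 1L) + 3L * a1))
    nt1 <- nt0 + 3L * plen
    if (decoy) nt0 <- nt1 <- NA_integer_
    rows[[p]] <- data.frame(peptide = searchable[p],
                            transcript_id = e$transcript_id,
                            frame = e$frame,
                            aa_start = a0, aa_end = a1,
                            nt_start = as.integer(nt0),
                            nt_end = as.integer(nt1),
                            is_decoy = decoy,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Build a decoy database by per-entry sequence reversal
#'
#' @param search_db ORF `data.frame` from [build_search_db()].
#' @return The same `data.frame` with every `aa_sequence` reversed.
#' @export
make_decoy_db <- function(search_db) {
  db <- search_db
  db$aa_sequence <- vapply(strsplit(db$aa_sequence, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
  db
}

#' Summarise protein-coding validation by peptide support
#'
#' Counts distinct non-decoy peptides per transcript (distinctness after
#' I/L collapse) and the numbers of transcripts with at least one and at
#' least two distinct peptides.
#'
#' @param hits `data.frame` from [match_peptides()].
#' @return List with `n_transcripts_ge1`, `n_transcripts_ge2`,
#'   `n_peptides` (distinct peptides overall) and `per_transcript`
#'   (`data.frame` of `transcript_id`, `n_peptides`).
#' @export
summarize_validation <- function(hits) {
  hits <- hits[!hits$is_decoy, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(list(n_transcripts_ge1 = 0L, n_transcripts_ge2 = 0L,
                n_peptides = 0L,
                per_transcript = data.frame(transcript_id = character(),
                                            n_peptides = integer(),
                                            stringsAsFactors = FALSE)))
  key <- unique(data.frame(transcript_id = hits$transcript_id,
                           peptide = .collapse_il(hits$peptide),
                           stringsAsFactors = FALSE))
  tab <- table(key$transcript_id)
  per <- data.frame(transcript_id = names(tab),
                    n_peptides = as.integer(tab),
                    stringsAsFactors = FALSE)
  per <- per[order(per$transcript_id), , drop = FALSE]
  rownames(per) <- NULL
  list(n_transcripts_ge1 = sum(per$n_peptides >= 1L),
       n_transcripts_ge2 = sum(per$n_peptides >= 2L),
       n_peptides = length(unique(key$peptide)),
       per_transcript = per)
}

#' Detect frameshifts from multi-frame peptide assignments
#'
#' Per transcript, non-decoy hits are ordered by nucleotide start and runs
#' of same-frame hits are collapsed into segments.  A frameshift is counted
#' at each adjacent pair of segments in different frames on the same strand
#' whose nucleotide spans do not overlap.  Transcripts whose peptides map
#' to both strands are reported with `mixed_strand = TRUE` and no shift
#' count: such assignments are assembly anomalies, not reading-frame
#' shifts.
#'
#' @param hits `data.frame` from [match_peptides()].
#' @return `data.frame` with one row per transcript that has either >= 1
#'   frameshift or mixed-strand evidence: `transcript_id`, `n_shifts`,
#'   `frame_path` (e.g. `"+1>+2>+1"`), `n_segments`, `n_peptides`,
#'   `mixed_strand`.
#' @export
detect_frameshifts <- function(hits) {
  empty <- data.frame(transcript_id = character(), n_shifts = integer(),
                      frame_path = character(), n_segments = integer(),
                      n_peptides = integer(), mixed_strand = logical(),
                      stringsAsFactors = FALSE)
  hits <- hits[!hits$is_decoy & !is.na(hits$nt_start), , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  out <- lapply(split(hits, hits$transcript_id), function(h) {
    tid <- h$transcript_id[1]
    n_pep <- length(unique(.collapse_il(h$peptide)))
    if (length(unique(sign(h$frame))) > 1L)
      return(data.frame(transcript_id = tid, n_shifts = NA_integer_,
                        frame_path = NA_character_, n_segments = NA_integer_,
                        n_peptides = n_pep, mixed_strand = TRUE,
                        stringsAsFactors = FALSE))
    h <- h[order(h$nt_start, h$nt_end, h$frame), , drop = FALSE]
    r <- rle(h$frame)
    seg_end_idx <- cumsum(r$lengths)
    seg_start_idx <- c(1L, utils::head(seg_end_idx, -1L) + 1L)
    seg <- data.frame(frame = r$values,
                      nt_start = vapply(seq_along(r$values), function(s)
                        min(h$nt_start[seg_start_idx[s]:seg_end_idx[s]]), integer(1)),
                      nt_end = vapply(seq_along(r$values), function(s)
                        max(h$nt_end[seg_start_idx[s]:seg_end_idx[s]]), integer(1)))
    # walk segments, keeping only transitions whose spans do not overlap
    path <- 1L
    for (s in seq_len(nrow(seg))[-1L]) {
      prev <- path[length(path)]
      if (seg$frame[s] != seg$frame[prev] && seg$nt_start[s] >= seg$nt_end[prev])
        path <- c(path, s)
    }
    n_shifts <- length(path) - 1L
    if (n_shifts == 0L) return(NULL)
    data.frame(transcript_id = tid, n_shifts = n_shifts,
               frame_path = paste(sprintf("%+d", seg$frame[path]), collapse = ">"),
               n_segments = length(path), n_peptides = n_pep,
               mixed_strand = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Target-decoy false discovery rate
#'
#' FDR is the number of distinct decoy peptide matches divided by the
#' number of distinct target peptide matches; the identification set passes
#' when FDR is strictly below the threshold.
#'
#' @param target_hits,decoy_hits `data.frame`s from [match_peptides()]
#'   against the target and the reversed decoy database.
#' @param threshold FDR acceptance threshold, default 0.01 (pass iff
#'   FDR < threshold).
#' @return List with `fdr`, `n_target`, `n_decoy`, `pass`.
#' @export
decoy_fdr <- function(target_hits, decoy_hits, threshold = 0.01) {
  n_t <- length(unique(.collapse_il(target_hits$peptide)))
  n_d <- length(unique(.collapse_il(decoy_hits$peptide)))
  fdr <- if (n_t == 0L && n_d == 0L) {
    0
  } else if (n_t == 0L) {
    warning("decoy matches without any target match; FDR reported as 1")
    1
  } else n_d / n_t
  list(fdr = fdr, n_target = n_t, n_decoy = n_d, pass = fdr < threshold)
}
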