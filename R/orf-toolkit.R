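# Six-frame translation, stop-to-stop ORF extraction and the >25 aa
# search database used for peptide matching.

.FRAMES <- c(1L, 2L, 3L, -1L, -2L, -3L)

# Translate every sequence of a DNAStringSet in one frame.
# frame is +1..+3 (forward) or -1..-3 (read from the reverse complement).
# Codons containing ambiguity codes become 'X'; stops are '*'.
.translate_frame <- function(set, frame) {
  f <- abs(frame)
  if (frame < 0) set <- Biostrings::reverseComplement(set)
  w <- Biostrings::width(set)
  usable <- pmax(0L, (w - f + 1L) %/% 3L) * 3L
  sub <- Biostrings::subseq(set, start = pmin(f, w + 1L), width = usable)
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Translate a transcript in all six reading frames
#'
#' Conceptual translation under the standard genetic code in the three
#' forward frames and the three frames of the reverse complement.  Stop
#' codons are rendered as `*`; codons containing IUPAC ambiguity codes are
#' rendered as `X`.  Frames too short to hold a codon yield empty strings.
#'
#' @param transcript A single DNA sequence ([Biostrings::DNAString],
#'   length-1 [Biostrings::DNAStringSet], or character scalar).
#' @return Named character vector of length 6 with names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @examples
#' six_frame_translate("ATGAAATAA")
#' @export
six_frame_translate <- function(transcript) {
  if (methods::is(transcript, "DNAString"))
    transcript <- Biostrings::DNAStringSet(transcript)
  set <- tryCatch(.as_dna_set(transcript, "transcript"),
                  error = function(e) stop(e))
  if (length(set) != 1L)
    stop("'transcript' must be a single sequence", call. = FALSE)
  out <- vapply(.FRAMES, function(f) .translate_frame(set, f)[1L], character(1))
  names(out) <- sprintf("%+d", .FRAMES)
  out
}

#' Extract stop-to-stop open reading frames
#'
#' ORFs are maximal stop-free stretches of the six-frame translation;
#' sequence ends count as boundaries and no start codon is required.
#' Ambiguity-derived `X` residues do not terminate an ORF.
#'
#' Nucleotide coordinates are 0-based half-open on the forward strand;
#' amino-acid coordinates are 0-based half-open on the frame's translation.
#'
#' @param transcripts DNA sequences ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @return A `data.frame` with one row per ORF: `transcript_id`, `frame`
#'   (integer, one of 1,2,3,-1,-2,-3), `nt_start`, `nt_end`, `aa_start`,
#'   `aa_end`, `aa_sequence`, `aa_length`, `transcript_length`.
#' @seealso [longest_orf()], [build_search_db()]
#' @export
extract_orfs <- function(transcripts) {
  set <- .as_dna_set(transcripts)
  ids <- names(set)
  L <- Biostrings::width(set)
  out <- vector("list", 6L)
  for (k in seq_along(.FRAMES)) {
    frame <- .FRAMES[k]
    f <- abs(frame)
    aa <- .translate_frame(set, frame)
    m <- gregexpr("[^*]+", aa)
    rows <- lapply(seq_along(aa), function(i) {
      st <- m[[i]]
      if (st[1] == -1L) return(NULL)
      len <- attr(st, "match.length")
      a0 <- as.integer(st) - 1L            # 0-based aa start
      a1 <- a0 + len
      if (frame > 0) {
        nt0 <- (f - 1L) + 3L * a0
        nt1 <- (f - 1L) + 3L * a1
      } else {
        nt0 <- L[i] - ((f - 1L) + 3L * a1)
        nt1 <- L[i] - ((f - 1L) + 3L * a0)
      }
      data.frame(transcript_id = ids[i], frame = frame,
                 nt_start = nt0, nt_end = nt1,
                 aa_start = a0, aa_end = a1,
                 aa_sequence = substring(aa[i], st, st + len - 1L),
                 aa_length = len,
                 transcript_length = L[i],
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      aa_start = integer(), aa_end = integer(),
                      aa_sequence = character(), aa_length = integer(),
                      transcript_length = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# canonical ORF ordering used for tie-breaks: frame order +1,+2,+3,-1,-2,-3
# then leftmost within the frame's translation
.orf_order <- function(orfs) {
  frame_rank <- match(orfs$frame, .FRAMES)
  order(-orfs$aa_length, frame_rank, orfs$aa_start)
}

#' Longest ORF per transcript
#'
#' Ties are broken by frame order `+1,+2,+3,-1,-2,-3`, then by the leftmost
#' position within the frame's translation.
#'
#' @param x Either a `data.frame` from [extract_orfs()] or sequences
#'   acceptable to it.
#' @return One row per transcript (same columns as [extract_orfs()]).
#'   Transcripts whose six translations are all stops contribute no row.
#' @export
longest_orf <- function(x) {
  orfs <- if (is.data.frame(x)) x else extract_orfs(x)
  if (nrow(orfs) == 0L) return(orfs)
  orfs <- orfs[.orf_order(orfs), , drop = FALSE]
  orfs <- orfs[!duplicated(orfs$transcript_id), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Build the peptide search database of ORFs longer than a minimum
#'
#' Retains stop-to-stop ORFs strictly longer than `min_aa - 1` residues
#' (default keeps ORFs of at least 26 aa, i.e. "longer than 25 amino
#' acids").  Each entry's FASTA-style header encodes transcript id, frame
#' and forward-strand nucleotide coordinates and can be parsed back with
#' [parse_orf_header()].
#'
#' @param transcripts Sequences acceptable to [extract_orfs()].
#' @param min_aa Minimum ORF length in residues that is retained
#'   (inclusive); default 26.
#' @return A `data.frame` as from [extract_orfs()] with an extra `header`
#'   column.
#' @export
build_search_db <- function(transcripts, min_aa = 26L) {
  .stopifnot_scalar_number(min_aa, "min_aa", lower = 1)
  orfs <- if (is.data.frame(transcripts)) transcripts else extract_orfs(transcripts)
  db <- orfs[orfs$aa_length >= min_aa, , drop = FALSE]
  db$header <- sprintf("%s|%+d|%d-%d", db$transcript_id, db$frame,
                       db$nt_start, db$nt_end)
  rownames(db) <- NULL
  db
}

#' @rdname build_search_db
#' @param header Character vector of headers written by [build_search_db()].
#' @return `parse_orf_header()`: a `data.frame` with `transcript_id`,
#'   `frame`, `nt_start`, `nt_end`.
#' @export
parse_orf_header <- function(header) {
  parts <- regmatches(header, regexec("^(.*)\\|([+-][123])\\|(\\d+)-(\\d+)$", header))
  bad <- vapply(parts, length, integer(1)) != 5L
  if (any(bad))
    stop("malformed ORF header(s): ", paste(header[bad], collapse = ", "),
         call. = FALSE)
  data.frame(transcript_id = vapply(parts, `[`, character(1), 2L),
             frame = as.integer(vapply(parts, `[`, character(1), 3L)),
             nt_start = as.integer(vapply(parts, `[`, character(1), 4L)),
             nt_end = as.integer(vapply(parts, `[`, character(1), 5L)),
             stringsAsFactors = FALSE)
}

#' Write a search database as protein FASTA
#'
#' @param db `data.frame` from [build_search_db()].
#' @param file Output path.
#' @return Invisibly, the [Biostrings::AAStringSet] written.
#' @export
write_search_db <- function(db, file) {
  aa <- Biostrings::AAStringSet(db$aa_sequence)
  names(aa) <- db$header
  Biostrings::writeXStringSet(aa, file)
  invisible(aa)
}

# Longest-ORF length (aa) per sequence without materialising the full ORF
# table; used by the coding-potential null model where only the maximum is
# needed.
.longest_orf_lengths <- function(set) {
  best <- integer(length(set))
  for (frame in .FRAMES) {
    aa <- .translate_frame(set, frame)
    m <- gregexpr("[^*]+", aa)
    lens <- vapply(m, function(st) {
      if (st[1] == -1L) 0L else max(attr(st, "match.length"))
    }, integer(1))
    best <- pmax(best, lens)
  }
  best
}
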