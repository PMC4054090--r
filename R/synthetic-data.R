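# Synthetic transcriptomes, peptide tables, homology hit tables and
# orthologue sets with known ground truth.

.SPECIFICITY_CLASSES <- c("conserved", "urodele_only", "no_hit")

# database -> taxon used by the synthetic hit tables and the annotation
# stage defaults
.DB_TAXON <- c(uniprot_mouse = "mouse", ncbi_nr = "multi",
               ncbi_nt = "multi", est_urodele = "urodele")

#' Configuration for the synthetic-data generator
#'
#' The defaults describe a desk-scale transcriptome that emulates the
#' statistical structure of a normalised multi-platform cDNA assembly:
#' coding transcripts with a 5'UTR--ORF--3'UTR layout, noncoding random
#' sequence, transcripts carrying implanted single-nucleotide indel
#' frameshifts, tryptic peptides sampled from the encoded proteins, and
#' homology hit tables whose e-value structure separates conserved,
#' urodele-only and no-hit transcripts.
#'
#' @param n_coding,n_noncoding,n_frameshifted Transcript counts per class
#'   (frameshifted transcripts are coding transcripts with implanted
#'   indels).
#' @param orf_length_range Min/max ORF length in amino acids (the encoded
#'   protein, including the initiator methionine; a stop codon is appended,
#'   so the ORF occupies `3*(aa+1)` nt).
#' @param utr_length_range Min/max UTR length in nt (drawn independently
#'   for the 5' and 3' UTR).
#' @param base_composition Named probabilities over A,C,G,T summing to 1;
#'   used for UTRs and noncoding sequence.
#' @param peptide_min_len,peptide_max_len Retained tryptic peptide length
#'   range in residues.
#' @param peptide_sampling_rate Probability that an in-silico peptide is
#'   "observed" (emulating MS detectability).
#' @param specificity_mix Named fractions over
#'   `conserved`, `urodele_only`, `no_hit`, summing to 1.
#' @param indels_per_transcript Min/max number of single-nucleotide indels
#'   implanted per frameshifted transcript.
#' @param keyword_fraction Fraction of generated hit descriptions that
#'   contain a low-quality keyword ('mRNA', 'cDNA', 'clone', 'genomic').
#' @param evalue_log10_conserved,evalue_log10_urodele log10 e-value
#'   intervals (uniform) for hits of the two annotated classes.
#' @param go_fraction Fraction of protein-database subjects that carry at
#'   least one GO term in the generated GO map.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_coding = 200L, n_noncoding = 100L,
                             n_frameshifted = 50L,
                             orf_length_range = c(100L, 300L),
                             utr_length_range = c(30L, 150L),
                             base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             peptide_min_len = 7L, peptide_max_len = 30L,
                             peptide_sampling_rate = 0.6,
                             specificity_mix = c(conserved = 0.7,
                                                 urodele_only = 0.15,
                                                 no_hit = 0.15),
                             indels_per_transcript = c(1L, 3L),
                             keyword_fraction = 0.2,
                             evalue_log10_conserved = c(-60, -21),
                             evalue_log10_urodele = c(-40, -16),
                             go_fraction = 0.8,
                             seed = 1L) {
  cfg <- list(n_coding = as.integer(n_coding),
              n_noncoding = as.integer(n_noncoding),
              n_frameshifted = as.integer(n_frameshifted),
              orf_length_range = as.integer(orf_length_range),
              utr_length_range = as.integer(utr_length_range),
              base_composition = base_composition,
              peptide_min_len = as.integer(peptide_min_len),
              peptide_max_len = as.integer(peptide_max_len),
              peptide_sampling_rate = peptide_sampling_rate,
              specificity_mix = specificity_mix,
              indels_per_transcript = as.integer(indels_per_transcript),
              keyword_fraction = keyword_fraction,
              evalue_log10_conserved = evalue_log10_conserved,
              evalue_log10_urodele = evalue_log10_urodele,
              go_fraction = go_fraction,
              seed = as.integer(seed))

  with(cfg, {
    if (any(c(n_coding, n_noncoding, n_frameshifted) < 0))
      stop("transcript counts must be >= 0", call. = FALSE)
    if (length(orf_length_range) != 2L || orf_length_range[1] < 2L ||
        orf_length_range[1] > orf_length_range[2])
      stop("'orf_length_range' must be a nonempty aa range with min >= 2",
           call. = FALSE)
    if (length(utr_length_range) != 2L || utr_length_range[1] < 0L ||
        utr_length_range[1] > utr_length_range[2])
      stop("'utr_length_range' must be a nonempty nt range", call. = FALSE)
    if (!identical(sort(names(base_composition)), sort(.DNA4)) ||
        abs(sum(base_composition) - 1) > 1e-9 ||
        any(base_composition < 0 | base_composition > 1))
      stop("'base_composition' must be 4 probabilities over A,C,G,T summing to 1",
           call. = FALSE)
    if (peptide_min_len < 1L || peptide_min_len > peptide_max_len)
      stop("invalid peptide length range", call. = FALSE)
    if (peptide_sampling_rate < 0 || peptide_sampling_rate > 1)
      stop("'peptide_sampling_rate' must be in [0,1]", call. = FALSE)
    if (!identical(sort(names(specificity_mix)), sort(.SPECIFICITY_CLASSES)) ||
        abs(sum(specificity_mix) - 1) > 1e-9 || any(specificity_mix < 0))
      stop("'specificity_mix' must be fractions over conserved/urodele_only/no_hit summing to 1",
           call. = FALSE)
    if (length(indels_per_transcript) != 2L || indels_per_transcript[1] < 1L ||
        indels_per_transcript[1] > indels_per_transcript[2])
      stop("'indels_per_transcript' must be a nonempty range with min >= 1",
           call. = FALSE)
    # frameshifted transcripts need room for spaced indels away from the
    # ORF ends
    if (n_frameshifted > 0L &&
        orf_length_range[1] < 16L + 12L * indels_per_transcript[2])
      stop("minimum ORF length too short to fit the configured indels",
           call. = FALSE)
  })
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:",
      x$n_coding, "coding /", x$n_noncoding, "noncoding /",
      x$n_frameshifted, "frameshifted transcripts, seed", x$seed, "\n")
  invisible(x)
}

# exact class counts from fractions: floor, then distribute the remainder
# to the largest fractional parts (ties in fixed class order)
.exact_class_counts <- function(n, mix) {
  mix <- mix[.SPECIFICITY_CLASSES]
  raw <- n * mix
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(-(raw - counts), seq_along(raw))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# sample k indel codon indices, one per stratum of the interior of the
# ORF, so indels stay spaced and away from the ORF ends
.sample_indel_codons <- function(orf_len, k) {
  lo <- 6L; hi <- orf_len - 8L
  bounds <- as.integer(floor(seq(lo, hi + 1L, length.out = k + 1L)))
  vapply(seq_len(k), function(j) {
    a <- bounds[j]; b <- max(a, bounds[j + 1L] - 12L)
    if (a >= b) a else sample(seq.int(a, b), 1L)
  }, integer(1))
}

#' Generate a synthetic transcriptome with ground truth
#'
#' Coding transcripts contain an ATG-initiated, stop-terminated ORF encoded
#' by uniformly chosen synonymous codons, flanked by UTRs drawn at the
#' configured base composition.  Frameshifted transcripts additionally
#' carry single-nucleotide insertions or deletions at recorded offsets
#' inside the ORF.  Noncoding transcripts are random sequence.
#'
#' @param config A [synthetic_config()].
#' @return List with `transcripts` (a named [Biostrings::DNAStringSet]) and
#'   `truth`, a `data.frame` with one row per transcript: `transcript_id`,
#'   `is_coding`, `is_frameshifted`, `orf_start`/`orf_end` (0-based
#'   half-open nt coordinates in the final sequence, `NA` for noncoding),
#'   `frameshift_positions` and `frameshift_codons` (list columns),
#'   `specificity_class`, `source_protein`.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .generate_transcriptome_impl(config))
}

.generate_transcriptome_impl <- function(cfg) {
  n_total <- cfg$n_coding + cfg$n_noncoding + cfg$n_frameshifted
  if (n_total == 0L)
    stop("config generates no transcripts", call. = FALSE)
  ids <- sprintf("TX%05d", seq_len(n_total))
  kind <- rep(c("coding", "noncoding", "frameshifted"),
              c(cfg$n_coding, cfg$n_noncoding, cfg$n_frameshifted))

  counts <- .exact_class_counts(n_total, cfg$specificity_mix)
  spec_class <- sample(rep(.SPECIFICITY_CLASSES, counts))

  codons <- .codon_table()
  rev_translate <- function(protein) {
    aa <- strsplit(protein, "")[[1]]
    paste(vapply(aa, function(a) {
      opts <- codons[[a]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1)), collapse = "")
  }
  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(seq.int(rng[1], rng[2]), 1L)
  rand_dna1 <- function(len) {
    if (len == 0L) return("")
    paste(sample(.DNA4, len, replace = TRUE, prob = cfg$base_composition[.DNA4]),
          collapse = "")
  }

  seqs <- character(n_total)
  truth <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    if (kind[i] == "noncoding") {
      orf_len <- rint(cfg$orf_length_range)
      total <- rint(cfg$utr_length_range) + 3L * (orf_len + 1L) +
        rint(cfg$utr_length_range)
      seqs[i] <- rand_dna1(total)
      truth[[i]] <- data.frame(transcript_id = ids[i], is_coding = FALSE,
                               is_frameshifted = FALSE,
                               orf_start = NA_integer_, orf_end = NA_integer_,
                               frameshift_positions = I(list(integer(0))),
                               frameshift_codons = I(list(integer(0))),
                               specificity_class = spec_class[i],
                               source_protein = NA_character_,
                               stringsAsFactors = FALSE)
      next
    }
    orf_len <- rint(cfg$orf_length_range)
    u5 <- rint(cfg$utr_length_range)
    u3 <- rint(cfg$utr_length_range)
    protein <- paste0("M", .random_protein(orf_len - 1L))
    orf_nt <- paste0(rev_translate(protein), sample(.STOP_CODONS, 1L))
    seq <- paste0(rand_dna1(u5), orf_nt, rand_dna1(u3))
    orf_start <- u5
    orf_end <- u5 + 3L * (orf_len + 1L)

    fs_pos <- integer(0)
    fs_codons <- integer(0)
    if (kind[i] == "frameshifted") {
      k <- rint(cfg$indels_per_transcript)
      fs_codons <- .sample_indel_codons(orf_len, k)
      # original nt position inside the codon (offset 1 or 2 keeps the
      # corrupted bases within that single codon)
      p_orig <- orf_start + 3L * fs_codons + sample(1:2, k, replace = TRUE)
      is_ins <- sample(c(TRUE, FALSE), k, replace = TRUE)
      chars <- strsplit(seq, "")[[1]]
      shift <- 0L
      fs_pos <- integer(k)
      for (j in seq_len(k)) {
        p <- p_orig[j] + shift               # 0-based position in current seq
        fs_pos[j] <- p
        if (is_ins[j]) {
          chars <- append(chars, sample(.DNA4, 1L), after = p)
          shift <- shift + 1L
        } else {
          chars <- chars[-(p + 1L)]
          shift <- shift - 1L
        }
      }
      seq <- paste(chars, collapse = "")
      orf_end <- orf_end + shift
    }
    seqs[i] <- seq
    truth[[i]] <- data.frame(transcript_id = ids[i], is_coding = TRUE,
                             is_frameshifted = kind[i] == "frameshifted",
                             orf_start = orf_start, orf_end = orf_end,
                             frameshift_positions = I(list(fs_pos)),
                             frameshift_codons = I(list(fs_codons)),
                             specificity_class = spec_class[i],
                             source_protein = protein,
                             stringsAsFactors = FALSE)
  }
  transcripts <- Biostrings::DNAStringSet(seqs)
  names(transcripts) <- ids
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(transcripts = transcripts, truth = truth)
}

#' In-silico tryptic digestion
#'
#' Cleaves after lysine (K) and arginine (R) except when the next residue
#' is proline (P).
#'
#' @param protein Amino-acid string (may be empty).
#' @return `data.frame` with `peptide`, `aa_start`, `aa_end` (0-based
#'   half-open coordinates on the protein).
#' @examples
#' tryptic_digest("MKRAAAK")$peptide   # "MK" "R" "AAAK"
#' tryptic_digest("MKPRA")$peptide     # "MKPR" "A" (no cleavage before P)
#' @export
tryptic_digest <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (is.na(protein) || nchar(protein) == 0L)
    return(data.frame(peptide = character(), aa_start = integer(),
                      aa_end = integer(), stringsAsFactors = FALSE))
  cuts <- gregexpr("(?<=[KR])(?!P)", protein, perl = TRUE)[[1]]
  cuts <- if (cuts[1] == -1L) integer(0) else as.integer(cuts) - 1L # 0-based
  starts <- c(0L, cuts)
  ends <- c(cuts, nchar(protein))
  keep <- ends > starts
  data.frame(peptide = substring(protein, starts[keep] + 1L, ends[keep]),
             aa_start = starts[keep], aa_end = ends[keep],
             stringsAsFactors = FALSE)
}

#' Digest source proteins and sample observed peptides
#'
#' Tryptic peptides of each coding transcript's source protein are length
#' filtered, peptides overlapping an implanted indel codon are dropped
#' (they no longer exist as contiguous translation products), and each
#' survivor is retained as "observed" with probability
#' `peptide_sampling_rate`.
#'
#' @param truth Truth table from [generate_transcriptome()].
#' @param config The [synthetic_config()] used to generate it.
#' @return `data.frame` with `transcript_id` (truth column), `peptide`,
#'   `aa_start`, `aa_end`, `segment` (0-based index of the inter-indel
#'   segment the peptide lies in) and `observed`.  Hand only the observed
#'   peptide sequences (see [observed_peptides()]) to the pipeline.
#' @export
digest_and_sample_peptides <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 1L, {
    rows <- lapply(which(truth$is_coding), function(i) {
      pep <- tryptic_digest(truth$source_protein[i])
      if (nrow(pep) == 0L) return(NULL)
      len <- pep$aa_end - pep$aa_start
      pep <- pep[len >= config$peptide_min_len & len <= config$peptide_max_len, ,
                 drop = FALSE]
      if (nrow(pep) == 0L) return(NULL)
      fc <- sort(truth$frameshift_codons[[i]])
      if (length(fc) > 0L) {
        hit_indel <- vapply(seq_len(nrow(pep)), function(j)
          any(fc >= pep$aa_start[j] & fc < pep$aa_end[j]), logical(1))
        pep <- pep[!hit_indel, , drop = FALSE]
        if (nrow(pep) == 0L) return(NULL)
      }
      pep$segment <- findInterval(pep$aa_start, fc)
      pep$transcript_id <- truth$transcript_id[i]
      pep
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
      return(data.frame(transcript_id = character(), peptide = character(),
                        aa_start = integer(), aa_end = integer(),
                        segment = integer(), observed = logical(),
                        stringsAsFactors = FALSE))
    tab$observed <- stats::runif(nrow(tab)) < config$peptide_sampling_rate
    rownames(tab) <- NULL
    tab[, c("transcript_id", "peptide", "aa_start", "aa_end", "segment",
            "observed")]
  })
}

#' @rdname digest_and_sample_peptides
#' @param peptide_table Output of `digest_and_sample_peptides()`.
#' @return `observed_peptides()`: character vector of unique observed
#'   peptide sequences (what an MS experiment would hand the pipeline).
#' @export
observed_peptides <- function(peptide_table) {
  sort(unique(peptide_table$peptide[peptide_table$observed]))
}

.CLEAN_DESCRIPTIONS <- c(
  "activin receptor type-1 precursor", "plectin isoform 1",
  "fascin actin-bundling protein", "collagen alpha-1 chain",
  "heat shock protein beta-1", "myosin heavy chain cardiac isoform",
  "S100 calcium binding protein", "EF-hand domain containing protein",
  "keratin type II cytoskeletal", "elongation factor 1-alpha",
  "crystallin beta A2", "fibronectin precursor",
  "matrix metalloproteinase-9", "tenascin-C isoform 2")

.LQ_KEYWORDS <- c("mRNA", "cDNA", "clone", "genomic")

.random_description <- function(n, keyword_fraction) {
  lq <- stats::runif(n) < keyword_fraction
  out <- character(n)
  out[!lq] <- sample(.CLEAN_DESCRIPTIONS, sum(!lq), replace = TRUE)
  if (any(lq)) {
    kw <- sample(.LQ_KEYWORDS, sum(lq), replace = TRUE)
    out[lq] <- sprintf("uncharacterized %s %s %d",
                       sample(c("liver", "heart", "larval", "testis"),
                              sum(lq), replace = TRUE),
                       kw, sample.int(9999, sum(lq), replace = TRUE))
  }
  out
}

.blast_rows <- function(qid, db, n, log10_range, keyword_fraction) {
  if (n == 0L)
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      description = character(), stringsAsFactors = FALSE))
  ev <- 10^stats::runif(n, log10_range[1], log10_range[2])
  alen <- sample(80:300, n, replace = TRUE)
  pid <- stats::runif(n, 70, 99)
  data.frame(qseqid = qid,
             sseqid = sprintf("%s_%06d", toupper(db), sample.int(999999, n)),
             pident = round(pid, 1),
             length = alen,
             mismatch = as.integer(round(alen * (1 - pid / 100))),
             gapopen = sample(0:3, n, replace = TRUE),
             qstart = 1L, qend = alen,
             sstart = 1L, send = alen,
             evalue = ev,
             bitscore = round(-2 * log10(ev) + stats::runif(n, 0, 5), 1),
             description = .random_description(n, keyword_fraction),
             stringsAsFactors = FALSE)
}

#' Generate homology hit tables per database
#'
#' Conserved transcripts receive hits below 1e-20 in the protein databases
#' (and, with probability 1/2, in the nucleotide database); urodele-only
#' transcripts receive hits only in the urodele EST table; no-hit
#' transcripts receive none.  A configurable fraction of description lines
#' contains a low-quality keyword.
#'
#' @inheritParams digest_and_sample_peptides
#' @return List with `tables` (named list of 12+1-column BLAST tabular
#'   `data.frame`s, one per database) and `go_map` (`data.frame` of
#'   `subject_id`, `go_terms`; semicolon-separated GO ids).
#' @export
generate_hit_tables <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 2L, {
    dbs <- names(.DB_TAXON)
    tables <- stats::setNames(
      lapply(dbs, function(d) .blast_rows(character(0), d, 0, c(-1, -1), 0)),
      dbs)
    for (cls in c("conserved", "urodele_only")) {
      idx <- which(truth$specificity_class == cls)
      for (i in idx) {
        qid <- truth$transcript_id[i]
        if (cls == "conserved") {
          for (d in c("uniprot_mouse", "ncbi_nr")) {
            n <- sample(1:3, 1L)
            tables[[d]] <- rbind(tables[[d]],
              .blast_rows(qid, d, n, config$evalue_log10_conserved,
                          config$keyword_fraction))
          }
          if (stats::runif(1) < 0.5)
            tables[["ncbi_nt"]] <- rbind(tables[["ncbi_nt"]],
              .blast_rows(qid, "ncbi_nt", sample(1:2, 1L),
                          config$evalue_log10_conserved,
                          config$keyword_fraction))
        } else {
          tables[["est_urodele"]] <- rbind(tables[["est_urodele"]],
            .blast_rows(qid, "est_urodele", sample(1:2, 1L),
                        config$evalue_log10_urodele,
                        config$keyword_fraction))
        }
      }
    }
    prot_subjects <- unique(c(tables$uniprot_mouse$sseqid, tables$ncbi_nr$sseqid))
    with_go <- prot_subjects[stats::runif(length(prot_subjects)) < config$go_fraction]
    go_map <- data.frame(
      subject_id = with_go,
      go_terms = vapply(seq_along(with_go), function(i)
        paste(sprintf("GO:%07d", sample.int(9999999, sample(1:3, 1L))),
              collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    list(tables = tables, go_map = go_map)
  })
}

#' Generate a synthetic orthologue hit set with known alignment fractions
#'
#' Every conserved coding transcript is paired with one orthologue subject
#' whose alignment fraction is drawn uniformly (default 0.3..1.1, so both
#' sides of the 0.75 full-length rule occur, including transcripts longer
#' than their orthologue).  Decoy one-directional hits are added so that
#' only reciprocal best pairs are planted truth.
#'
#' @inheritParams digest_and_sample_peptides
#' @param fraction_range Range of planted alignment fractions.
#' @return List with `query_hits`, `subject_hits` (BLAST-like tables),
#'   `subject_lengths` (`data.frame` of `subject_id`, `length`) and
#'   `truth` (`data.frame` of `query_id`, `subject_id`, `align_fraction`,
#'   `full_length`).
#' @export
generate_ortholog_tables <- function(truth, config,
                                     fraction_range = c(0.3, 1.1)) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 3L, {
    idx <- which(truth$is_coding & truth$specificity_class == "conserved")
    n <- length(idx)
    qids <- truth$transcript_id[idx]
    sids <- sprintf("ORTH_%05d", seq_len(n))
    slen <- as.integer(round(nchar(truth$source_protein[idx]) *
                               stats::runif(n, 0.85, 1.15)))
    slen <- pmax(slen, 30L)
    frac <- stats::runif(n, fraction_range[1], fraction_range[2])
    alen <- pmax(1L, as.integer(round(frac * slen)))
    ev <- 10^stats::runif(n, -80, -30)
    bs <- round(-2 * log10(ev), 1)
    q2s <- data.frame(qseqid = qids, sseqid = sids, pident = 90,
                      length = alen, mismatch = 0L, gapopen = 0L,
                      qstart = 1L, qend = alen, sstart = 1L, send = alen,
                      evalue = ev, bitscore = bs,
                      stringsAsFactors = FALSE)
    s2q <- data.frame(qseqid = sids, sseqid = qids, pident = 90,
                      length = alen, mismatch = 0L, gapopen = 0L,
                      qstart = 1L, qend = alen, sstart = 1L, send = alen,
                      evalue = ev, bitscore = bs,
                      stringsAsFactors = FALSE)
    # decoy non-reciprocal hits: each query also hits some other subject,
    # at a clearly worse e-value
    if (n > 1L) {
      other <- sids[c(seq.int(2L, n), 1L)]
      dec <- q2s
      dec$sseqid <- other
      dec$evalue <- dec$evalue * 1e10
      dec$bitscore <- round(dec$bitscore / 2, 1)
      q2s <- rbind(q2s, dec)
    }
    list(query_hits = q2s, subject_hits = s2q,
         subject_lengths = data.frame(subject_id = sids, length = slen,
                                      stringsAsFactors = FALSE),
         truth = data.frame(query_id = qids, subject_id = sids,
                            align_fraction = alen / slen,
                            full_length = alen / slen > 0.75,
                            stringsAsFactors = FALSE))
  })
}

#' Flatten per-database hit tables into one annotation hit table
#'
#' @param tables Named list of BLAST tabular `data.frame`s (12 standard
#'   columns plus `description`), e.g. from [generate_hit_tables()].
#' @param db_taxon Optional named character vector mapping database name to
#'   taxon; defaults to the synthetic databases' mapping, with `"unknown"`
#'   for unmapped names.
#' @return `data.frame` with `query_id`, `database`, `taxon`, `subject_id`,
#'   `description`, `evalue`, `bitscore`, `align_length`.
#' @export
as_annotation_hits <- function(tables, db_taxon = .DB_TAXON) {
  rows <- lapply(names(tables), function(d) {
    t <- tables[[d]]
    if (nrow(t) == 0L) return(NULL)
    data.frame(query_id = t$qseqid, database = d,
               taxon = if (d %in% names(db_taxon)) unname(db_taxon[d]) else "unknown",
               subject_id = t$sseqid,
               description = if ("description" %in% names(t)) t$description else "",
               evalue = t$evalue, bitscore = t$bitscore,
               align_length = t$length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(), database = character(),
                      taxon = character(), subject_id = character(),
                      description = character(), evalue = numeric(),
                      bitscore = numeric(), align_length = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
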