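orfs_of <- function(seqs, min_aa = 1) build_search_db(seqs, min_aa = min_aa)

test_that("peptide matching reports frame, aa and nt coordinates", {
  hits <- match_peptides("MK", orfs_of(c(t1 = "ATGAAATAA")))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$frame, 1L)
  expect_equal(c(hits$aa_start, hits$aa_end), c(0L, 2L))
  expect_equal(c(hits$nt_start, hits$nt_end), c(0L, 6L))
  expect_false(hits$is_decoy)
})

test_that("I/L equivalence, X exclusion and absent peptides behave", {
  # CTG AAA -> "LK"; peptide IK must hit under I/L equivalence only
  db <- orfs_of(c(t1 = "CTGAAA"))
  expect_equal(nrow(match_peptides("IK", db)), 1)
  expect_equal(match_peptides("IK", db)$peptide, "IK")
  expect_equal(nrow(match_peptides("IK", db, il_equivalent = FALSE)), 0)
  expect_equal(nrow(match_peptides("WWW", db)), 0)
  expect_equal(nrow(match_peptides("MXK", orfs_of(c(t1 = "ATGNNNAAA")))), 0)
  expect_error(match_peptides("MK2", db), "invalid residue")
})

test_that("overlapping occurrences are all reported", {
  # AAA AAA AAA -> "KKK"; peptide KK occurs at offsets 0 and 1
  hits <- match_peptides("KK", orfs_of(c(t1 = "AAAAAAAAA")))
  expect_equal(sum(hits$frame == 1), 2)
  expect_setequal(hits$aa_start[hits$frame == 1], c(0L, 1L))
})

test_that("hit coordinates round-trip through re-translation", {
  cfg <- small_synth(seed = 41, peptide_sampling_rate = 1)
  g <- generate_transcriptome(cfg)
  pt <- digest_and_sample_peptides(g$truth, cfg)
  db <- build_search_db(g$transcripts)
  hits <- match_peptides(observed_peptides(pt), db)
  il <- function(x) chartr("I", "L", x)
  for (k in sample(nrow(hits), min(50, nrow(hits)))) {
    tr <- six_frame_translate(g$transcripts[[hits$transcript_id[k]]])
    frame_aa <- unname(tr[sprintf("%+d", hits$frame[k])])
    slice <- substr(frame_aa, hits$aa_start[k] + 1, hits$aa_end[k])
    expect_equal(il(slice), il(hits$peptide[k]))
    # nt span is consistent with the aa span
    expect_equal(hits$nt_end[k] - hits$nt_start[k],
                 3 * nchar(hits$peptide[k]))
  }
})

test_that("validation counts distinct peptides only", {
  # transcript encodes K-rich protein so the same peptide occurs twice
  db <- orfs_of(c(t1 = "GCTGCTAAAGCTGCTAAA"))   # "AAKAAK"
  hits <- match_peptides("AAK", db)
  expect_gte(nrow(hits), 2)
  v <- summarize_validation(hits)
  expect_equal(v$n_transcripts_ge1, 1)
  expect_equal(v$n_transcripts_ge2, 0)
  expect_equal(v$n_peptides, 1)

  hits2 <- match_peptides(c("AAK", "KAA"), db)
  v2 <- summarize_validation(hits2)
  expect_equal(v2$n_transcripts_ge2, 1)
})

test_that("frameshift detection on constructed multi-frame hits", {
  h <- data.frame(peptide = c("AAAAAAAAAA", "CCCCCCCCCC"),
                  transcript_id = "t1", frame = c(1L, 2L),
                  aa_start = c(0L, 11L), aa_end = c(10L, 21L),
                  nt_start = c(0L, 33L), nt_end = c(30L, 63L),
                  is_decoy = FALSE, stringsAsFactors = FALSE)
  fs <- detect_frameshifts(h)
  expect_equal(fs$n_shifts, 1)
  expect_equal(fs$frame_path, "+1>+2")

  one_frame <- h; one_frame$frame <- 1L
  expect_equal(nrow(detect_frameshifts(one_frame)), 0)

  mixed <- h; mixed$frame <- c(1L, -2L)
  fsm <- detect_frameshifts(mixed)
  expect_true(fsm$mixed_strand)
  expect_true(is.na(fsm$n_shifts))
})

test_that("synthetic frameshifts are called exactly when segments are covered", {
  cfg <- synthetic_config(n_coding = 0, n_noncoding = 0, n_frameshifted = 12,
                          orf_length_range = c(150, 250),
                          utr_length_range = c(20, 60),
                          peptide_sampling_rate = 1, seed = 42)
  g <- generate_transcriptome(cfg)
  pt <- digest_and_sample_peptides(g$truth, cfg)
  db <- build_search_db(g$transcripts)
  hits <- match_peptides(observed_peptides(pt), db)
  fs <- detect_frameshifts(hits)
  called <- setNames(fs$n_shifts, fs$transcript_id)
  obs <- pt[pt$observed, ]
  for (i in seq_len(nrow(g$truth))) {
    tid <- g$truth$transcript_id[i]
    k <- length(g$truth$frameshift_positions[[i]])
    covered <- length(unique(obs$segment[obs$transcript_id == tid])) == k + 1
    got <- if (tid %in% names(called)) unname(called[tid]) else 0L
    if (covered) expect_equal(got, k, info = tid)
    else expect_lte(got, k)   # never over-called
  }
})

test_that("decoy FDR resolves the <1% boundary strictly", {
  fake <- function(n, prefix) data.frame(
    peptide = sprintf("%s%04d", prefix, seq_len(max(n, 1))),
    transcript_id = "t", frame = 1L, aa_start = 0L, aa_end = 4L,
    nt_start = 0L, nt_end = 12L, is_decoy = prefix == "D",
    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  expect_true(decoy_fdr(fake(99, "T"), fake(0, "D"))$pass)
  expect_equal(decoy_fdr(fake(99, "T"), fake(0, "D"))$fdr, 0)
  at_boundary <- decoy_fdr(fake(100, "T"), fake(1, "D"))
  expect_equal(at_boundary$fdr, 0.01)
  expect_false(at_boundary$pass)
  below <- decoy_fdr(fake(200, "T"), fake(1, "D"))
  expect_equal(below$fdr, 0.005)
  expect_true(below$pass)
  expect_warning(res <- decoy_fdr(fake(0, "T"), fake(1, "D")), "decoy")
  expect_equal(res$fdr, 1)
})

test_that("full recovery and clean decoys on an unshifted synthetic set", {
  cfg <- synthetic_config(n_coding = 20, n_noncoding = 5, n_frameshifted = 0,
                          orf_length_range = c(80, 150),
                          utr_length_range = c(20, 60),
                          peptide_sampling_rate = 1, seed = 43)
  g <- generate_transcriptome(cfg)
  pt <- digest_and_sample_peptides(g$truth, cfg)
  db <- build_search_db(g$transcripts)
  hits <- match_peptides(observed_peptides(pt), db)
  il <- function(x) chartr("I", "L", x)
  obs_key <- unique(paste(il(pt$peptide), pt$transcript_id))
  hit_key <- unique(paste(il(hits$peptide), hits$transcript_id))
  expect_true(all(obs_key %in% hit_key))          # recall = 1
  decoys <- match_peptides(observed_peptides(pt), make_decoy_db(db),
                           decoy = TRUE)
  is_pal <- function(p) { q <- il(p)
    q == paste(rev(strsplit(q, "")[[1]]), collapse = "") }
  long_nonpal <- decoys[nchar(decoys$peptide) >= 5 &
                          !vapply(decoys$peptide, is_pal, logical(1)), ]
  expect_equal(nrow(long_nonpal), 0)
})
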