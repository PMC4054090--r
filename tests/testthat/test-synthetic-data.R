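test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_coding = -1), "counts")
  expect_error(synthetic_config(base_composition = c(A = .5, C = .5, G = 0, T = .1)),
               "sum")
  expect_error(synthetic_config(orf_length_range = c(50, 20)), "orf_length_range")
  expect_error(synthetic_config(peptide_sampling_rate = 1.5), "sampling_rate")
  expect_error(synthetic_config(specificity_mix = c(conserved = 1, urodele_only = 0.5,
                                                    no_hit = -0.5)), "fractions")
  # indels cannot fit into a tiny ORF
  expect_error(synthetic_config(orf_length_range = c(20, 30), n_frameshifted = 1),
               "too short")
})

test_that("degenerate counts and the length construction rule hold", {
  g0 <- generate_transcriptome(synthetic_config(n_coding = 0, n_noncoding = 1,
                                                n_frameshifted = 0, seed = 1))
  expect_equal(length(g0$transcripts), 1)
  expect_false(g0$truth$is_coding)

  cfg <- synthetic_config(n_coding = 1, n_noncoding = 0, n_frameshifted = 0,
                          orf_length_range = c(100, 100),
                          utr_length_range = c(50, 50), seed = 2)
  g1 <- generate_transcriptome(cfg)
  # 5'UTR + (100 aa + stop) codons + 3'UTR
  expect_equal(Biostrings::width(g1$transcripts), 50 + 3 * 101 + 50)
  expect_equal(g1$truth$orf_start, 50)
  expect_equal(g1$truth$orf_end, 50 + 3 * 101)
})

test_that("generation is byte-identical for identical seeds", {
  cfg <- small_synth(seed = 5)
  g1 <- generate_transcriptome(cfg)
  g2 <- generate_transcriptome(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  Biostrings::writeXStringSet(g1$transcripts, f1)
  Biostrings::writeXStringSet(g2$transcripts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(g1$truth, g2$truth)
})

test_that("class counts in truth equal the configured counts exactly", {
  cfg <- synthetic_config(n_coding = 17, n_noncoding = 9, n_frameshifted = 3,
                          specificity_mix = c(conserved = 0.5,
                                              urodele_only = 0.3, no_hit = 0.2),
                          seed = 6)
  g <- generate_transcriptome(cfg)
  expect_equal(sum(g$truth$is_coding & !g$truth$is_frameshifted), 17)
  expect_equal(sum(!g$truth$is_coding), 9)
  expect_equal(sum(g$truth$is_frameshifted), 3)
  counts <- table(g$truth$specificity_class)
  expect_equal(unname(counts[c("conserved", "urodele_only", "no_hit")]),
               txproteo:::.exact_class_counts(29, cfg$specificity_mix),
               ignore_attr = TRUE)
})

test_that("implanted ORFs translate back to the source protein", {
  cfg <- small_synth(seed = 7)
  g <- generate_transcriptome(cfg)
  plain <- g$truth[g$truth$is_coding & !g$truth$is_frameshifted, ]
  for (i in seq_len(nrow(plain))) {
    s <- as.character(g$transcripts[[plain$transcript_id[i]]])
    orf_nt <- substr(s, plain$orf_start[i] + 1, plain$orf_end[i])
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf_nt),
                                             no.init.codon = TRUE))
    expect_equal(sub("\\*$", "", aa), plain$source_protein[i])
    expect_equal(substr(orf_nt, 1, 3), "ATG")
  }
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("MKRAAAK")$peptide, c("MK", "R", "AAAK"))
  expect_equal(tryptic_digest("MKPRA")$peptide, c("MKPR", "A"))
  expect_equal(nrow(tryptic_digest("")), 0)
  d <- tryptic_digest("MKRAAAK")
  expect_equal(substring("MKRAAAK", d$aa_start + 1, d$aa_end), d$peptide)
})

test_that("peptide sampling respects the rate and the length filter", {
  cfg0 <- small_synth(seed = 8, peptide_sampling_rate = 0)
  g <- generate_transcriptome(cfg0)
  pt0 <- digest_and_sample_peptides(g$truth, cfg0)
  expect_equal(length(observed_peptides(pt0)), 0)
  cfg1 <- small_synth(seed = 8, peptide_sampling_rate = 1)
  pt1 <- digest_and_sample_peptides(g$truth, cfg1)
  expect_true(all(pt1$observed))
  len <- pt1$aa_end - pt1$aa_start
  expect_true(all(len >= cfg1$peptide_min_len & len <= cfg1$peptide_max_len))
})

test_that("every observed peptide is a substring of a six-frame translation", {
  cfg <- small_synth(seed = 9, peptide_sampling_rate = 1)
  g <- generate_transcriptome(cfg)
  pt <- digest_and_sample_peptides(g$truth, cfg)
  obs <- pt[pt$observed, ]
  for (i in sample(nrow(obs), min(60, nrow(obs)))) {
    tr <- six_frame_translate(g$transcripts[[obs$transcript_id[i]]])
    expect_true(any(vapply(tr, grepl, logical(1), pattern = obs$peptide[i],
                           fixed = TRUE)),
                info = paste(obs$transcript_id[i], obs$peptide[i]))
  }
})

test_that("hit tables follow the specificity classes", {
  cfg <- small_synth(seed = 10)
  g <- generate_transcriptome(cfg)
  ht <- generate_hit_tables(g$truth, cfg)
  hits <- as_annotation_hits(ht$tables)
  for (i in seq_len(nrow(g$truth))) {
    id <- g$truth$transcript_id[i]
    mine <- hits[hits$query_id == id, ]
    cls <- g$truth$specificity_class[i]
    if (cls == "no_hit") {
      expect_equal(nrow(mine), 0)
    } else if (cls == "urodele_only") {
      expect_true(nrow(mine) >= 1)
      expect_true(all(mine$database == "est_urodele"))
    } else {
      expect_true(any(mine$database %in% c("uniprot_mouse", "ncbi_nr") &
                        mine$evalue <= 1e-20))
    }
  }
})

test_that("keyword fraction 1 makes every description low quality", {
  cfg <- small_synth(seed = 12, keyword_fraction = 1)
  g <- generate_transcriptome(cfg)
  ht <- generate_hit_tables(g$truth, cfg)
  hits <- as_annotation_hits(ht$tables)
  flagged <- filter_hits(hits, cutoff = 1)
  expect_true(all(flagged$low_quality))
})

test_that("hit tables survive a BLAST-tabular round trip", {
  cfg <- small_synth(seed = 13)
  g <- generate_transcriptome(cfg)
  ht <- generate_hit_tables(g$truth, cfg)
  tab <- ht$tables$uniprot_mouse
  f <- tempfile()
  write_blast_tabular(tab, f)
  back <- read_blast_tabular(f)
  expect_equal(back$qseqid, tab$qseqid)
  expect_equal(back$evalue, tab$evalue, tolerance = 1e-10)
  expect_equal(back$description, tab$description)
})
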