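test_that("six-frame translation matches hand-worked examples", {
  expect_equal(unname(six_frame_translate("ATG")[1]), "M")
  tr <- six_frame_translate("ATGAAATAA")
  expect_equal(unname(tr["+1"]), "MK*")
  expect_equal(unname(tr["-1"]), "LFH")
  expect_equal(unname(six_frame_translate("ATG")[c("+2", "+3")]),
               c("", ""))
  expect_error(six_frame_translate("ATQG"))
})

test_that("negative frames equal forward frames of the reverse complement", {
  withr::with_seed(21, {
    for (i in 1:25) {
      s <- rand_dna_str(sample(3:200, 1))
      tr <- six_frame_translate(s)
      tr_rc <- six_frame_translate(revcomp_str(s))
      expect_equal(unname(tr[c("-1", "-2", "-3")]),
                   unname(tr_rc[c("+1", "+2", "+3")]))
    }
  })
})

test_that("ambiguity codons translate to X and do not terminate ORFs", {
  tr <- six_frame_translate("ATGNNNAAA")
  expect_equal(unname(tr["+1"]), "MXK")
  o <- extract_orfs(c(t1 = "ATGNNNAAA"))
  expect_equal(max(o$aa_length[o$frame == 1]), 3)
})

test_that("ORF extraction matches the positional oracle on small cases", {
  lo <- longest_orf(c(t1 = "ATGAAATAA"))
  expect_equal(lo$frame, -1L)
  expect_equal(lo$aa_sequence, "LFH")
  expect_equal(lo$aa_length, 3L)
  # all-stop +1 frame contributes no +1 ORF
  o <- extract_orfs(c(t1 = "TAATAATAA"))
  expect_false(any(o$frame == 1))
})

test_that("ORF records are consistent: coordinates, no stops, slices", {
  withr::with_seed(22, {
    set <- Biostrings::DNAStringSet(setNames(
      vapply(1:20, function(i) rand_dna_str(sample(30:400, 1)), character(1)),
      paste0("s", 1:20)))
    orfs <- extract_orfs(set)
    expect_true(all(orfs$nt_end - orfs$nt_start == 3 * orfs$aa_length))
    expect_true(all(orfs$nt_start >= 0))
    expect_true(all(orfs$nt_end <= orfs$transcript_length))
    expect_false(any(grepl("*", orfs$aa_sequence, fixed = TRUE)))
    # each ORF is the literal slice of its frame's translation
    for (k in sample(nrow(orfs), 40)) {
      tr <- six_frame_translate(set[[orfs$transcript_id[k]]])
      frame_aa <- unname(tr[sprintf("%+d", orfs$frame[k])])
      expect_equal(substr(frame_aa, orfs$aa_start[k] + 1, orfs$aa_end[k]),
                   orfs$aa_sequence[k])
    }
  })
})

test_that("longest ORF agrees with the exhaustive oracle on random sequences", {
  withr::with_seed(23, {
    for (i in 1:60) {
      s <- rand_dna_str(sample(10:600, 1))
      lo <- longest_orf(c(x = s))
      got <- if (nrow(lo) == 0) 0L else lo$aa_length
      expect_equal(got, oracle_longest_orf(s))
    }
  })
})

test_that("appending a stop codon never increases the longest ORF", {
  withr::with_seed(24, {
    for (i in 1:20) {
      s <- rand_dna_str(sample(30:300, 1))
      base <- longest_orf(c(x = s))$aa_length
      ext <- longest_orf(c(x = paste0(s, "TAA")))$aa_length
      expect_lte(ext, base + 1)  # +1 only via frame re-phasing of the tail
    }
  })
})

test_that("search database applies the >25 aa rule at the boundary", {
  # stop + 25 codons + stop: longest ORF exactly 25 aa -> excluded
  orf25 <- paste0("TAA", strrep("GCT", 25), "TAA")
  orf26 <- paste0("TAA", strrep("GCT", 26), "TAA")
  db25 <- build_search_db(c(t1 = orf25))
  db26 <- build_search_db(c(t1 = orf26))
  expect_false(any(db25$aa_length == 25 & db25$frame == 1))
  expect_true(any(db26$aa_length == 26 & db26$frame == 1))
})

test_that("ORF headers round-trip and name the right translation slice", {
  withr::with_seed(25, {
    set <- Biostrings::DNAStringSet(setNames(
      vapply(1:10, function(i) rand_dna_str(300), character(1)),
      paste0("tx", 1:10)))
    db <- build_search_db(set, min_aa = 10)
    parsed <- parse_orf_header(db$header)
    expect_equal(parsed$transcript_id, db$transcript_id)
    expect_equal(parsed$frame, db$frame)
    expect_equal(parsed$nt_start, db$nt_start)
    expect_equal(parsed$nt_end, db$nt_end)
    expect_error(parse_orf_header("oops"), "malformed")
    # every entry is a substring of exactly the frame named in its header
    for (k in seq_len(nrow(db))) {
      tr <- six_frame_translate(set[[db$transcript_id[k]]])
      in_frame <- grepl(db$aa_sequence[k], tr[sprintf("%+d", db$frame[k])],
                        fixed = TRUE)
      expect_true(in_frame)
    }
  })
})
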