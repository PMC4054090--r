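mk_hits <- function(evalue, description = "some protein", query_id = "q1",
                    database = "ncbi_nr", taxon = "multi",
                    subject_id = sprintf("S%03d", seq_along(evalue)),
                    bitscore = 100) {
  data.frame(query_id = query_id, database = database, taxon = taxon,
             subject_id = subject_id, description = description,
             evalue = evalue, bitscore = bitscore, align_length = 100L,
             stringsAsFactors = FALSE)
}

test_that("e-value cutoff is inclusive at e-15 and keywords flag quality", {
  h <- mk_hits(c(1e-16, 1e-14, 1e-15),
               description = c("collagen alpha", "hypothetical mRNA clone 42",
                               "fibronectin"))
  f <- filter_hits(h, cutoff = 1e-15)
  expect_setequal(f$evalue, c(1e-16, 1e-15))
  expect_false(any(f$evalue == 1e-14))
  f2 <- filter_hits(h, cutoff = 1e-10)
  expect_true(f2$low_quality[f2$evalue == 1e-14])
  expect_false(any(f2$low_quality[f2$evalue != 1e-14]))
})

test_that("malformed rows are dropped with a count, not an error", {
  h <- mk_hits(c(1e-20, NA, -1))
  expect_message(f <- filter_hits(h, 1e-15), "2 malformed")
  expect_equal(nrow(f), 1)
  expect_equal(attr(f, "n_malformed"), 2)
})

test_that("filtering is monotone in the cutoff", {
  withr::with_seed(51, {
    h <- mk_hits(10^runif(200, -40, -5))
    strict <- filter_hits(h, 1e-20)
    loose <- filter_hits(h, 1e-10)
    expect_true(all(strict$subject_id %in% loose$subject_id))
  })
})

test_that("functional assignment picks the best GO-bearing hit", {
  h <- mk_hits(c(1e-30, 1e-25), subject_id = c("NOGO", "HASGO"))
  gm <- data.frame(subject_id = "HASGO", go_terms = "GO:0001234")
  sel <- select_best_annotation(h, gm)
  expect_equal(sel$assignments$subject_id, "HASGO")
  expect_equal(sel$assignments$evalue, 1e-25)
  expect_equal(sel$assignments$go_terms, "GO:0001234")
  # no GO-bearing hit: annotated but functionally unassigned
  sel0 <- select_best_annotation(h, NULL)
  expect_equal(nrow(sel0$assignments), 0)
  expect_equal(nrow(sel0$top_hits), 2)
})

test_that("top-k retains exactly k hits in rating order", {
  h <- mk_hits(c(1e-30, 1e-10, 1e-50, 1e-20, 1e-40))
  sel <- select_best_annotation(h, NULL, k = 3)
  expect_equal(nrow(sel$top_hits), 3)
  expect_equal(sel$top_hits$evalue, c(1e-50, 1e-40, 1e-30))
  # ties on e-value resolved by descending bitscore
  ht <- mk_hits(rep(1e-30, 2), bitscore = c(50, 90))
  sel2 <- select_best_annotation(ht, NULL, k = 1)
  expect_equal(sel2$top_hits$bitscore, 90)
})

test_that("functional cutoff is stricter than retention", {
  h <- mk_hits(1e-18, subject_id = "HASGO")
  gm <- data.frame(subject_id = "HASGO", go_terms = "GO:0000001")
  sel <- select_best_annotation(h, gm, functional_cutoff = 1e-20)
  expect_equal(nrow(sel$assignments), 0)     # survives e-15 but not e-20
  expect_equal(nrow(sel$top_hits), 1)
})

test_that("a step-function annotation truth yields L50 at the step", {
  lens <- setNames(rep(seq(25, 975, by = 50), each = 4),
                   sprintf("q%03d", 1:80))
  annotated <- names(lens)[lens >= 300]
  hits <- mk_hits(rep(1e-30, length(annotated)), query_id = annotated)
  rc <- annotation_rate_curve(lens, hits, cutoffs = 1e-15)
  expect_equal(rc$summary$l50, 300)
  # all annotated -> L50 = first nonempty bin
  hits_all <- mk_hits(rep(1e-30, length(lens)), query_id = names(lens))
  rc2 <- annotation_rate_curve(lens, hits_all, cutoffs = 1e-15)
  expect_equal(rc2$summary$l50, min(rc2$curves$bin_start))
  expect_error(annotation_rate_curve(lens, hits, cutoffs = numeric(0)),
               "nonempty")
})

test_that("L50 is non-decreasing as the cutoff tightens", {
  withr::with_seed(52, {
    lens <- setNames(sample(100:1500, 300, replace = TRUE),
                     sprintf("q%03d", 1:300))
    # annotation probability grows with length; e-values vary
    ann <- names(lens)[runif(300) < pmin(1, lens / 1000)]
    hits <- mk_hits(10^runif(length(ann), -40, -8), query_id = ann)
    rc <- annotation_rate_curve(lens, hits, cutoffs = c(1e-10, 1e-15, 1e-25))
    l50 <- rc$summary$l50[order(rc$summary$cutoff, decreasing = TRUE)]
    l50 <- l50[!is.na(l50)]
    expect_true(all(diff(l50) >= 0))
  })
})

test_that("the >=400 bp rate does exact bookkeeping on synthetic truth", {
  cfg <- small_synth(seed = 53)
  g <- generate_transcriptome(cfg)
  ht <- generate_hit_tables(g$truth, cfg)
  hits <- as_annotation_hits(ht$tables)
  rc <- annotation_rate_curve(g$transcripts, hits, cutoffs = 1e-15,
                              length_filter = 400)
  lens <- Biostrings::width(g$transcripts)
  ge <- lens >= 400
  # the generator gives every conserved/urodele transcript at least one
  # hit that survives e-15, and no-hit transcripts none
  with_hits <- g$truth$specificity_class != "no_hit"
  expect_equal(rc$summary$rate_ge_filter, mean(with_hits[ge]))
})
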