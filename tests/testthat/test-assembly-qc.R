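test_that("N50 matches hand-worked and degenerate cases", {
  expect_equal(compute_n50(975), 975)
  expect_equal(compute_n50(c(7, 5, 3, 3, 2, 2, 2)), 5)
  expect_equal(compute_n50(c(10, 10)), 10)
  expect_error(compute_n50(numeric(0)), "empty")
})

test_that("N50 agrees with the brute-force all-cut-points oracle", {
  withr::with_seed(42, {
    for (i in 1:200) {
      lens <- sample.int(5000, sample(1:80, 1), replace = TRUE)
      expect_equal(compute_n50(lens), oracle_n50(lens))
    }
  })
})

test_that("length histogram uses half-open 50 bp bins and conserves counts", {
  h <- length_histogram(c(49, 50), bin_width = 50)
  expect_equal(h$count[h$bin_start == 0], 1)
  expect_equal(h$count[h$bin_start == 50], 1)
  expect_equal(nrow(length_histogram(numeric(0))), 0)
  withr::with_seed(1, {
    lens <- sample.int(1000, 1000, replace = TRUE)
    h <- length_histogram(lens, 50)
    expect_equal(sum(h$count), 1000)
    # counting oracle per bin
    for (k in seq_len(nrow(h)))
      expect_equal(h$count[k],
                   sum(lens >= h$bin_start[k] & lens < h$bin_end[k]))
  })
})

test_that("assembly stats length classes are monotone", {
  withr::with_seed(3, {
    s <- assembly_stats(sample.int(2000, 500, replace = TRUE))
    expect_true(s$n_ge_400 >= s$n_ge_500)
    expect_true(s$n_ge_500 >= s$n_ge_1000)
    expect_true(s$n50 <= 2000)
  })
})

make_set <- function(seqs) {
  Biostrings::DNAStringSet(setNames(seqs, sprintf("t%02d", seq_along(seqs))))
}

test_that("identical sequences cluster, unrelated sequences do not", {
  withr::with_seed(5, {
    a <- rand_dna_str(500)
    b <- rand_dna_str(500)
    cl <- greedy_redundancy_cluster(make_set(c(a, a, b)))
    expect_equal(nrow(cl), 3)
    expect_equal(length(unique(cl$cluster_id)), 2)
    same <- cl$cluster_id[cl$member_id %in% c("t01", "t02")]
    expect_equal(same[1], same[2])
  })
})

test_that("containment links at 25 nt flanks and splits at 40 nt", {
  withr::with_seed(6, {
    core <- rand_dna_str(400)
    inside <- paste0(rand_dna_str(25), core, rand_dna_str(25))
    cl <- greedy_redundancy_cluster(make_set(c(core, inside)))
    expect_equal(length(unique(cl$cluster_id)), 1)

    lopsided <- paste0(rand_dna_str(40), core, rand_dna_str(25))
    cl2 <- greedy_redundancy_cluster(make_set(c(core, lopsided)))
    expect_equal(length(unique(cl2$cluster_id)), 2)
  })
})

test_that("clustering is invariant to input order and strand flips", {
  withr::with_seed(7, {
    base <- rand_dna_str(600)
    seqs <- c(base,
              mutate_dna(base, 0.05),                 # ~95% identity copy
              substr(base, 21, 580),                  # contained fragment
              rand_dna_str(500), rand_dna_str(450))
    set <- make_set(seqs)
    ref <- greedy_redundancy_cluster(set)
    partition <- function(cl) {
      unname(lapply(split(cl$member_id, cl$cluster_id), sort))
    }
    perm <- sample(length(set))
    expect_equal(partition(greedy_redundancy_cluster(set[perm])),
                 partition(ref))
    flipped <- set
    flipped[[2]] <- Biostrings::reverseComplement(set[[2]])
    expect_equal(partition(greedy_redundancy_cluster(flipped)),
                 partition(ref))
  })
})

test_that("re-clustering representatives yields singletons", {
  withr::with_seed(8, {
    base <- rand_dna_str(500)
    set <- make_set(c(base, mutate_dna(base, 0.03),
                      rand_dna_str(500), rand_dna_str(480)))
    cl <- greedy_redundancy_cluster(set)
    reps <- cluster_representatives(cl, set)
    cl2 <- greedy_redundancy_cluster(reps)
    expect_equal(length(unique(cl2$cluster_id)), length(reps))
  })
})

test_that("representative is the longest member with lexicographic ties", {
  withr::with_seed(9, {
    core <- rand_dna_str(400)
    longer <- paste0(rand_dna_str(10), core, rand_dna_str(10))
    cl <- greedy_redundancy_cluster(make_set(c(core, longer)))
    expect_equal(cl$member_id[cl$is_representative], "t02")
  })
})
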