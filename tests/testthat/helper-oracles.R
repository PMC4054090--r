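# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different algorithms from the package code
# (plain codon-table lookups, brute-force enumeration, regex engines).

rand_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_aa_str <- function(n) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# point-mutate a DNA string at a given per-base rate
mutate_dna <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# --- N50 oracle: brute force over all distinct lengths -----------------
oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  cands <- sort(unique(lengths))
  ok <- vapply(cands, function(N) sum(lengths[lengths >= N]) >= half,
               logical(1))
  max(cands[ok])
}

# --- translation / longest-ORF oracle: plain codon-table scan ----------
oracle_translate_frame <- function(seq, frame) {
  if (frame < 0) seq <- revcomp_str(seq)
  f <- abs(frame)
  n <- nchar(seq)
  n_codons <- max(0, (n - f + 1) %/% 3)
  if (n_codons == 0) return("")
  starts <- f + 3 * (seq_len(n_codons) - 1)
  codons <- substring(seq, starts, starts + 2)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"   # any codon containing an ambiguity code
  paste(aa, collapse = "")
}

oracle_longest_orf <- function(seq) {
  best <- 0L
  for (frame in c(1, 2, 3, -1, -2, -3)) {
    aa <- oracle_translate_frame(seq, frame)
    if (!nzchar(aa)) next
    runs <- rle(strsplit(aa, "")[[1]] != "*")
    cand <- runs$lengths[runs$values]
    if (length(cand) > 0) best <- max(best, cand)
  }
  best
}

# --- PROSITE -> regex oracle ------------------------------------------
prosite_to_regex <- function(pattern) {
  e <- pattern$elements
  paste(vapply(seq_len(nrow(e)), function(i) {
    switch(e$type[i],
           fixed = e$residues[i],
           class = sprintf("[%s]", e$residues[i]),
           wildcard = sprintf(".{%d,%d}", e$min_rep[i], e$max_rep[i]))
  }, character(1)), collapse = "")
}

# all greedy matches of a pattern at every start, via the regex engine
oracle_scan <- function(pattern, seq) {
  rx <- sprintf("^(?:%s)", prosite_to_regex(pattern))
  n <- nchar(seq)
  out <- list()
  for (start in 0:max(0, n - pattern$min_span)) {
    tail <- substr(seq, start + 1, n)
    m <- regexpr(rx, tail, perl = TRUE)
    if (m == 1L) {
      len <- attr(m, "match.length")
      out[[length(out) + 1L]] <- data.frame(start = start, end = start + len)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer()))
  do.call(rbind, out)
}

# the novel-family motif used across the pattern tests
FAMILY_MOTIF <- paste0(
  "(L-x(1,3)-C-L-x(2)-[AL]-L-x(3)-[AL]-[AET]-x(2)-[LV]-x-[AS]-[ILV]-x-",
  "[DQ]-[LV]-[LV]-C-[AC]-[FIV]-x(3)-[DN]-[EP]-[AIV]-[EK]-x-K-[EN]-x-L)")

# --- small synthetic run shared by several tests -----------------------
small_synth <- function(seed = 11, ...) {
  synthetic_config(n_coding = 12, n_noncoding = 6, n_frameshifted = 4,
                   orf_length_range = c(80, 150),
                   utr_length_range = c(20, 60),
                   seed = seed, ...)
}
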