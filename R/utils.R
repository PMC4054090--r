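# Shared internal helpers.

# The 20 standard amino acids (one-letter), used for validation and for
# random protein generation.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.DNA4 <- c("A", "C", "G", "T")

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# codons per amino acid under the standard genetic code, for reverse
# translation in the synthetic-data generator
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# Draw random DNA sequences at the given per-base probabilities.
# Uses the caller's RNG stream; callers needing reproducibility wrap the
# call in withr::with_seed().
.random_dna <- function(lengths, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(all(lengths >= 0), abs(sum(probs) - 1) < 1e-6)
  total <- sum(lengths)
  bases <- sample(.DNA4, total, replace = TRUE, prob = probs)
  starts <- cumsum(c(1, lengths[-length(lengths)]))
  seqs <- vapply(seq_along(lengths), function(i) {
    if (lengths[i] == 0L) return("")
    paste(bases[starts[i]:(starts[i] + lengths[i] - 1L)], collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

.random_protein <- function(n_residues) {
  paste(sample(.AA20, n_residues, replace = TRUE), collapse = "")
}

# Coerce character / DNAStringSet input to a named DNAStringSet.
.as_dna_set <- function(x, arg = "transcripts") {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (!methods::is(x, "DNAStringSet"))
    stop(sprintf("'%s' must be a DNAStringSet or character vector", arg),
         call. = FALSE)
  if (is.null(names(x))) names(x) <- sprintf("seq%04d", seq_along(x))
  if (anyDuplicated(names(x)))
    stop(sprintf("'%s' must have unique names", arg), call. = FALSE)
  x
}

.as_aa_set <- function(x, arg = "proteins") {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  if (!methods::is(x, "AAStringSet"))
    stop(sprintf("'%s' must be an AAStringSet or character vector", arg),
         call. = FALSE)
  if (is.null(names(x))) names(x) <- sprintf("prot%04d", seq_along(x))
  x
}
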