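---
title: "Validating a de novo transcriptome with peptide evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a de novo transcriptome with peptide evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txproteo)
```

## Overview

When a transcriptome is assembled de novo — no reference genome, contigs
pooled from several sequencing platforms and assemblers — three questions
decide whether it can serve as a reference resource. Is the pool
redundant? Which transcripts actually encode protein, and which encode it
brokenly (indel frameshifts introduced by the assembly)? And which coding
transcripts are genuinely specific to the organism rather than simply
unannotated? `txproteo` answers these with sequence statistics, a
random-sequence null model for coding potential, and — the decisive
evidence — exact matching of mass-spectrometry-identified peptides to the
six-frame translation of every transcript.

This vignette explains each model and the design decisions behind it,
what the synthetic-data generator emulates, and what the tests do and do
not establish about real data.

## Assembly QC and redundancy clustering

**N50** is the smallest length N such that transcripts of length >= N
jointly contain at least half of all assembled bases. The accumulating
transcript's own length counts before the half-way comparison; that
convention matches common assembly-stats tools and resolves the tie at an
exact half, where verbal definitions are ambiguous.

**Redundancy clustering** merges near-identical contigs from different
assemblers. Two transcripts are linked when a local alignment (either
strand) reaches at least `min_identity = 0.90` over the aligned region
and leaves at most `max_overhang = 30` unmatched bases at *every*
sequence end. The every-end reading makes the rule a near-global-overlap
criterion: a short sequence contained in a longer one links only when the
containing sequence's flanks are also short, which is the observable
behavior of EST-clustering pipelines in this situation and the reading
consistent with the worked boundary cases the package tests (25 nt flanks
link, a 40 nt flank does not). Clusters are transitive closures
(single linkage) of these links, mirroring cluster-then-assemble EST
pipelines. The representative is the longest member (ties:
lexicographically smallest id) — a deliberate simplification: base-level
consensus calling is out of scope, and the merge's observable effect, one
sequence per redundancy group, is preserved. Ambiguous bases never count
as alignment matches. A shared-k-mer prefilter (`k = 16`, canonical
k-mers so strand flips cannot change candidacy) keeps the pairwise stage
at desk scale; the alignment itself is `Biostrings::pairwiseAlignment`.

## ORFs and the coding-potential null model

Transcripts are translated in six frames; stop codons render as `*` and
any codon containing an IUPAC ambiguity code renders as `X`. An **ORF**
here is a maximal stop-free stretch (stop-to-stop, sequence ends count as
boundaries) — *not* ATG-anchored, because a peptide search database must
also cover truncated 5' ends and frameshifted segments. `X` does not
terminate an ORF, but peptides never match across an `X` (an unknown
residue cannot support an identification). The **search database** keeps
ORFs longer than 25 aa (i.e. >= 26), the conventional floor below which
six-frame entries contribute mostly noise; the boundary is tested
exactly.

The **coding-potential test** compares each transcript's longest ORF with
random DNA of the same number and length. Because longest-ORF length
grows with transcript length, the comparison is made per 50 bp length
bin: the report gives, per bin, the null maximum and the count and
fraction of real transcripts strictly exceeding it. Null base composition
defaults to the mononucleotide frequencies of the input pool
(`composition = "matched"`); uniform composition is available. The
per-bin design is a declared choice; a `global = TRUE` variant collapses
the comparison without claiming it reproduces any particular published
figure. Calibration is tested by drawing the "real" set from the null
generator itself: by exchangeability, each real transcript exceeds the
maximum of n null transcripts with probability 1/(n+1) minus a tie
correction, and the suite checks the observed total against a 10,000-draw
Monte-Carlo estimate of that expectation within three standard
deviations.

## Peptide evidence, frameshifts, FDR

Identified peptides are matched as exact substrings of the search
database under **I/L equivalence** (leucine and isoleucine are
isobaric and indistinguishable by standard MS; configurable via
`il_equivalent`). Spectrum scoring is out of scope — the pipeline
consumes already-identified peptide strings. Every occurrence is
reported, including overlapping ones, with coordinates on the frame's
translation and mapped forward-strand nucleotide coordinates; the
round trip (re-translating the nucleotide span) is property-tested.

A transcript with at least two distinct peptides (distinct after I/L
collapse) is called protein coding; the >= 1 tier is also reported.
**Frameshifts** are called per transcript from the ordered non-decoy
hits: runs of same-frame hits collapse into segments, and each adjacent
segment pair in different frames on the same strand with non-overlapping
nucleotide spans counts one shift. At least one peptide per segment is
therefore required — the floor below which a shift is invisible. Peptides
on both strands of one transcript are reported as anomalies
(`mixed_strand`) and not counted as shifts, since a real reading-frame
shift continues on the same strand. **FDR** uses a per-entry reversed
decoy database: FDR = distinct decoy matches / distinct target matches,
passing strictly below 1%. Reversal does not preserve tryptic termini;
for substring matching this simple decoy is adequate and is validated by
the absence of non-palindromic decoy matches on synthetic data.

One boundary interaction is worth knowing: a peptide lying in a short
frameshift segment whose stop-to-stop ORF is below 26 aa is excluded with
its ORF from the search database, so exhaustive-digestion recall can fall
marginally below 1 on frameshifted transcripts and a fully covered shift
can occasionally be undercalled. This is the 26 aa rule behaving as
specified, not a matching failure.

## Annotation filtering and rate curves

Homology hits are retained at `evalue <= cutoff` (default 1e-15,
inclusive — a declared convention). Hits whose description contains a
low-quality keyword ('mRNA', 'cDNA', 'clone', 'genomic';
case-insensitive substring, word-boundary matching optional) are flagged
but kept, so downstream stages can choose. Per (query, taxon, database)
the top 3 hits by ascending e-value (ties: descending bitscore, then
subject id — "best-rated" is not defined beyond e-value usage, so the
tiebreak is declared) are retained; the functional assignment per taxon
is the best-rated hit carrying at least one GO term, at the stricter
1e-20 functional cutoff.

The **annotation-rate curve** bins transcripts at 50 bp and reports, per
e-value cutoff, the fraction with at least one surviving hit. `L50` is
the smallest bin start at which the rate reaches 0.5, scanning ascending,
without requiring the rate to stay above 0.5 afterwards. Per-bin rates
are the default; a tail-cumulative variant (`cumulative = TRUE`, rate
among transcripts at least as long as the bin start) is exposed because
the per-bin/cumulative choice is genuinely open. The summary also reports
the rate among transcripts >= 400 bp, the length filter separating
mostly-coding from mostly-unknown sequence.

## Orthologue fullness

Orthologues are assigned by **reciprocal best hit** — each sequence is
the other's best hit (lowest e-value, bitscore tiebreak). The underlying
"recursive best mapping" idea admits several readings; RBH is the
standard conservative proxy, and a one-directional variant is available
(`reciprocal = FALSE`). A pair is **full length** when the alignment
covers strictly more than 75% of the orthologue (subject) length;
fractions above 1 are legitimate, as de novo transcripts are often
somewhat longer than their orthologues. The 0.75/0.76 boundary is tested
exactly.

## Specificity and novel-protein analysis

Peptide-verified transcripts partition into `no_hit` (no surviving hit
anywhere), `urodele_only` (all surviving hits from databases designated
organism-group-specific) and `annotated`. Candidates — putative novel
proteins — are the peptide-verified members of the first two classes.
The class is computed from whatever filtered decision table is supplied,
so the e-value cutoff in force is part of the run's manifest.

The **PROSITE engine** supports the dialect needed for family motifs:
fixed residues, residue classes `[...]`, wildcards `x`, `x(n)`,
`x(m,n)`, `-` separators. Terminal anchors, negated classes and
non-wildcard repeats are rejected loudly rather than half-supported.
Scanning tries every start (overlapping matches are reported) and
resolves flexible wildcards greedily, longest repeat first — the same
semantics as a greedy regular expression, which is exactly how the
scanner is cross-checked in the tests. Candidate proteins are clustered
by single linkage on pairwise local alignment (BLOSUM62) with
`min_identity = 0.35` over the aligned region and coverage of at least
0.6 of the shorter sequence; profile-iteration search adds no testable
surface at desk scale and is deliberately replaced by this direct
similarity clustering. Clusters of two or more members are putative
families.

## The synthetic-data generator

`synthetic_config()` describes the study conditions the tests run under:

- 200 coding / 100 noncoding / 50 frameshifted transcripts by default;
  ORFs of 100–300 aa (ATG-initiated, stop-terminated, uniformly chosen
  synonymous codons) flanked by 30–150 nt UTRs; noncoding transcripts are
  random sequence of comparable length at the configured base
  composition (uniform by default).
- Frameshifts are single-nucleotide insertions or deletions (1–3 per
  transcript, spaced inside the ORF) — the minimal event that moves
  peptides between reading frames. Positions and affected codons are
  recorded in the truth table.
- Peptides are tryptic (cleave after K/R, not before P), length-filtered
  to 7–30 aa — 7 is the conventional minimum for confident MS
  identification — and observed with probability
  `peptide_sampling_rate` (0.6 by default, emulating MS detectability;
  1 in the validation-condition runs). Peptides overlapping an indel
  codon are dropped: they do not exist as contiguous translation
  products.
- Hit tables give conserved transcripts protein-database hits with
  log10 e-values uniform on [-60, -21] (always below the 1e-20
  functional tier), urodele-only transcripts hits only in the urodele
  EST table on [-40, -16] (always surviving 1e-15), and no-hit
  transcripts nothing; a configurable fraction of description lines
  carries a low-quality keyword. An orthologue table plants one
  reciprocal pair per conserved coding transcript with alignment
  fractions uniform on [0.3, 1.1], plus non-reciprocal decoy hits.

What the generator does *not* emulate: read-level sequencing error,
abundance structure and coverage-dependent fragmentation, chimeric
misassemblies, spectral noise and incorrect peptide identifications, and
biological homology between distinct transcripts. Passing tests
therefore demonstrate that the computations are correct and calibrated
under known ground truth — not that any particular recovery rate will be
achieved on real tissue data, where detectability and assembly error
dominate. Transcript length and abundance distributions of normalized
libraries are not asserted; the generator exposes ranges instead.

## Numerical and engineering choices

- Determinism: every stochastic step is seeded (`withr::with_seed`), and
  sub-seeds for the digest, hit and orthologue generators are derived by
  small offsets from the configured seed; identical configs give
  byte-identical outputs, and reports contain no timestamps.
- Tie-breaks are total everywhere (frame order then leftmost for longest
  ORFs; e-value, bitscore, subject id for hit rating; length then id for
  cluster representatives), so results are independent of input order.
- Degenerate inputs: empty peptide tables, empty hit tables and empty
  protein lists flow through as empty results; an empty transcript set
  for N50 and malformed PROSITE patterns are explicit errors; malformed
  hit rows are counted and dropped, not fatal.
- Scale: default test and acceptance runs use a 350-transcript pool,
  ~2,400 unique peptides and a ~6,500-entry ORF database — chosen as the
  size at which every property (including the 10,000-draw null
  calibration) is statistically meaningful on a single desktop core.
- The command-line surface is the R API itself plus
  `scripts/acceptance.R`; as an analysis package used from R, no shell
  wrapper is shipped.

## Using the pipeline

```r
run <- run_synthetic_pipeline(
  synthetic_config(n_coding = 40, n_noncoding = 20, n_frameshifted = 10,
                   peptide_sampling_rate = 1, seed = 7),
  pipeline_config(run_clustering = FALSE))
run$report$stats$n50
run$report$validation$n_transcripts_ge2
run$evaluation$specificity[c("precision", "recall")]
```

For real data, call `run_pipeline()` with a `DNAStringSet` of
transcripts, the identified peptide strings, per-database BLAST tabular
tables (`read_blast_tabular()`), an optional GO map, orthologue hit
tables and PROSITE pattern strings. Every threshold lives in
`pipeline_config()` and is echoed into the report manifest together with
per-stage record counts.
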