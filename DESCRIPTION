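Package: txproteo
Title: Proteogenomic Validation and Novelty Discovery for De Novo
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality assessment and protein-level validation of de novo
    assembled transcriptomes. Provides assembly summary statistics (N50,
    length-class counts) and greedy redundancy clustering of contig pools;
    six-frame translation, stop-to-stop ORF extraction and a coding-potential
    test against length-matched random null sequences; exact matching of mass
    spectrometry identified peptides to six-frame translations with
    frameshift detection from multi-frame peptide assignments and
    target-decoy FDR control; e-value and keyword based filtering of homology
    hit tables with annotation-rate-versus-length curves; reciprocal-best-hit
    orthologue pairing with alignment-fraction full-length calls;
    species-specificity classification, PROSITE-style motif scanning and
    similarity clustering of candidate novel proteins. A synthetic-data
    module generates transcriptomes, tryptic peptide tables, homology hit
    tables and orthologue sets with known ground truth so that every stage
    can be tested end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
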