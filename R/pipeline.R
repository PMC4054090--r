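# End-to-end orchestration: assembly QC -> ORF search database ->
# peptide validation -> annotation -> orthologues -> specificity.

#' Pipeline configuration with the validated default thresholds
#'
#' Defaults: annotation e-value cutoff `1e-15`, functional (GO) cutoff
#' `1e-20`, 400 bp length filter, 90% clustering identity with 30 bp
#' overhang, ORFs of at least 26 aa in the search database, full-length
#' alignment fraction 0.75 (strict), decoy FDR threshold 1% (strict),
#' 50 bp length bins.
#'
#' @param evalue_cutoff Annotation e-value cutoff.
#' @param functional_cutoff Functional-assignment e-value cutoff.
#' @param length_filter Length filter in bp.
#' @param min_identity,max_overhang,kmer Redundancy-clustering parameters.
#' @param min_orf_aa Minimum ORF length (aa) retained in the search db.
#' @param full_length_frac Orthologue full-length fraction threshold.
#' @param fdr_threshold Decoy FDR acceptance threshold.
#' @param bin_width Length bin width in bp.
#' @param curve_cutoffs Cutoffs for the annotation-rate curve.
#' @param urodele_dbs Database names designated urodele-only.
#' @param keywords Low-quality description keywords.
#' @param il_equivalent Treat I/L as equivalent in peptide matching.
#' @param min_peptides Distinct peptides required for "peptide verified".
#' @param null_replicates,null_composition Coding-potential null model
#'   settings.
#' @param run_clustering Run redundancy clustering (can be disabled for
#'   pools known to be non-redundant).
#' @param seed Seed for the null model stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_cutoff = 1e-15,
                            functional_cutoff = 1e-20,
                            length_filter = 400L,
                            min_identity = 0.90, max_overhang = 30L,
                            kmer = 16L,
                            min_orf_aa = 26L,
                            full_length_frac = 0.75,
                            fdr_threshold = 0.01,
                            bin_width = 50L,
                            curve_cutoffs = c(1e-10, 1e-15, 1e-20),
                            urodele_dbs = "est_urodele",
                            keywords = c("mRNA", "cDNA", "clone", "genomic"),
                            il_equivalent = TRUE,
                            min_peptides = 1L,
                            null_replicates = 1L,
                            null_composition = "matched",
                            run_clustering = TRUE,
                            seed = 1L) {
  cfg <- list(evalue_cutoff = evalue_cutoff,
              functional_cutoff = functional_cutoff,
              length_filter = as.integer(length_filter),
              min_identity = min_identity,
              max_overhang = as.integer(max_overhang),
              kmer = as.integer(kmer),
              min_orf_aa = as.integer(min_orf_aa),
              full_length_frac = full_length_frac,
              fdr_threshold = fdr_threshold,
              bin_width = as.integer(bin_width),
              curve_cutoffs = curve_cutoffs,
              urodele_dbs = urodele_dbs,
              keywords = keywords,
              il_equivalent = isTRUE(il_equivalent),
              min_peptides = as.integer(min_peptides),
              null_replicates = as.integer(null_replicates),
              null_composition = null_composition,
              run_clustering = isTRUE(run_clustering),
              seed = as.integer(seed))
  stopifnot(cfg$evalue_cutoff > 0, cfg$functional_cutoff > 0,
            cfg$length_filter >= 0, cfg$min_identity > 0,
            cfg$min_identity <= 1, cfg$max_overhang >= 0,
            cfg$min_orf_aa >= 1, cfg$full_length_frac >= 0,
            cfg$fdr_threshold > 0, cfg$bin_width >= 1,
            length(cfg$curve_cutoffs) >= 1, cfg$min_peptides >= 1,
            cfg$null_replicates >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the validation pipeline end to end
#'
#' Stages: assembly statistics, redundancy clustering, ORF search database
#' construction, peptide matching with frameshift detection and decoy FDR,
#' annotation filtering with rate curves and GO assignment, orthologue
#' full-length calling, specificity classification with optional motif
#' scanning and novel-protein clustering.  The report includes a three-way
#' cross-tabulation (length filter x annotated x peptide verified) and a
#' manifest with every parameter and per-stage record counts.
#'
#' @param transcripts [Biostrings::DNAStringSet] or named character
#'   vector of assembled transcripts.
#' @param peptides Character vector of identified peptide sequences (may
#'   be empty).
#' @param hit_tables Named list of BLAST tabular `data.frame`s per
#'   database, or a single pre-flattened annotation hit `data.frame`.
#' @param go_map Optional GO map (`subject_id`, `go_terms`).
#' @param orthologs Optional list with `query_hits`, `subject_hits`,
#'   `subject_lengths` for the orthologue stage.
#' @param patterns Optional character vector of PROSITE-syntax patterns
#'   scanned against candidate novel proteins.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; per-stage TSV outputs and a JSON
#'   summary are written there.
#' @return List of class `pipeline_report`; see Details in the package
#'   vignette.
#' @export
run_pipeline <- function(transcripts, peptides, hit_tables,
                         go_map = NULL, orthologs = NULL, patterns = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set <- .as_dna_set(transcripts)
  counts <- list(input_transcripts = length(set))

  ## stage: assembly statistics
  stats <- assembly_stats(set)
  hist <- length_histogram(set, config$bin_width)

  ## stage: redundancy clustering
  if (config$run_clustering) {
    clusters <- greedy_redundancy_cluster(set, config$min_identity,
                                          config$max_overhang, config$kmer)
    reps <- cluster_representatives(clusters, set)
  } else {
    clusters <- data.frame(cluster_id = sprintf("CL%05d", seq_along(set)),
                           member_id = names(set),
                           is_representative = TRUE,
                           stringsAsFactors = FALSE)
    reps <- set
  }
  counts$unique_transcripts <- length(reps)

  ## stage: ORF search database
  search_db <- build_search_db(reps, config$min_orf_aa)
  counts$search_db_entries <- nrow(search_db)

  ## stage: peptide evidence
  peptides <- unique(as.character(peptides))
  hits <- match_peptides(peptides, search_db,
                         il_equivalent = config$il_equivalent)
  decoy_hits <- match_peptides(peptides, make_decoy_db(search_db),
                               il_equivalent = config$il_equivalent,
                               decoy = TRUE)
  validation <- summarize_validation(hits)
  frameshifts <- detect_frameshifts(hits)
  fdr <- decoy_fdr(hits, decoy_hits, config$fdr_threshold)
  counts$peptides_in <- length(peptides)
  counts$peptides_matched <- validation$n_peptides
  counts$transcripts_verified <- validation$n_transcripts_ge1

  ## stage: annotation
  ann_hits <- if (is.data.frame(hit_tables)) hit_tables else as_annotation_hits(hit_tables)
  filtered <- filter_hits(ann_hits, config$evalue_cutoff, config$keywords)
  selection <- select_best_annotation(filtered, go_map,
                                      functional_cutoff = config$functional_cutoff)
  curve <- annotation_rate_curve(reps, ann_hits, config$curve_cutoffs,
                                 config$bin_width, config$length_filter)
  counts$hits_in <- nrow(ann_hits)
  counts$hits_retained <- nrow(filtered)
  counts$queries_annotated <- length(unique(filtered$query_id))

  ## stage: coding-potential null model on long non-annotated transcripts
  lens <- Biostrings::width(reps)
  annotated_ids <- unique(filtered$query_id)
  sel <- lens >= config$length_filter & !(names(reps) %in% annotated_ids)
  excess <- NULL
  if (any(sel))
    excess <- coding_potential_excess(reps[sel],
                                      n_replicates = config$null_replicates,
                                      composition = config$null_composition,
                                      seed = config$seed,
                                      bin_width = config$bin_width)

  ## stage: orthologues
  ortholog_pairs <- NULL
  if (!is.null(orthologs)) {
    pairs <- reciprocal_best_pairs(orthologs$query_hits, orthologs$subject_hits)
    ortholog_pairs <- call_full_length(pairs, orthologs$subject_lengths,
                                       config$full_length_frac)
    counts$ortholog_pairs <- nrow(ortholog_pairs)
  }

  ## stage: specificity / novelty
  verified <- validation$per_transcript
  verified_ids <- verified$transcript_id[verified$n_peptides >= config$min_peptides]
  specificity <- classify_specificity(filtered, names(reps), verified_ids,
                                      urodele_dbs = config$urodele_dbs)
  candidates <- specificity$transcript_id[specificity$candidate]
  counts$candidates <- length(candidates)

  candidate_proteins <- NULL
  pattern_matches <- NULL
  novel_clusters <- NULL
  if (length(candidates) > 0L) {
    lo <- longest_orf(extract_orfs(reps[candidates]))
    candidate_proteins <- stats::setNames(lo$aa_sequence, lo$transcript_id)
    if (!is.null(patterns)) {
      pattern_matches <- do.call(rbind, lapply(seq_along(patterns), function(pi) {
        m <- scan_pattern(patterns[pi], candidate_proteins)
        if (nrow(m) > 0L) m$pattern <- pi
        m
      }))
    }
    if (length(candidate_proteins) >= 2L)
      novel_clusters <- cluster_novel_proteins(candidate_proteins)
  }

  ## report: three-way partition (Venn-style cross-tabulation)
  ids <- names(reps)
  part <- data.frame(ge_length = lens >= config$length_filter,
                     annotated = ids %in% annotated_ids,
                     verified = ids %in% verified_ids)
  crosstab <- as.data.frame(table(ge_length = part$ge_length,
                                  annotated = part$annotated,
                                  verified = part$verified),
                            stringsAsFactors = FALSE)
  crosstab$Freq <- as.integer(crosstab$Freq)

  report <- structure(list(
    stats = stats, histogram = hist, clusters = clusters,
    search_db = search_db,
    peptide_hits = hits, decoy_hits = decoy_hits,
    validation = validation, frameshifts = frameshifts, fdr = fdr,
    filtered_hits = filtered, annotation = selection, curve = curve,
    coding_excess = excess,
    ortholog_pairs = ortholog_pairs,
    specificity = specificity,
    candidate_proteins = candidate_proteins,
    pattern_matches = pattern_matches,
    novel_clusters = novel_clusters,
    crosstab = crosstab,
    manifest = c(unclass(config), counts)),
    class = "pipeline_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:\n")
  cat("  transcripts:", x$stats$n_transcripts, "(N50", x$stats$n50, "nt)\n")
  cat("  search db:  ", nrow(x$search_db), "ORFs\n")
  cat("  verified:   ", x$validation$n_transcripts_ge1, "transcripts (>=1 peptide),",
      x$validation$n_transcripts_ge2, "(>=2)\n")
  cat("  frameshifts:", if (is.null(x$frameshifts)) 0 else
    sum(!x$frameshifts$mixed_strand), "transcripts\n")
  cat("  FDR:        ", signif(x$fdr$fdr, 3),
      if (x$fdr$pass) "(pass)" else "(fail)", "\n")
  cat("  candidates: ", x$manifest$candidates, "specific novel proteins\n")
  invisible(x)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$clusters, file.path(out_dir, "clusters.tsv"))
  write_tsv(report$search_db, file.path(out_dir, "search_db.tsv"))
  write_tsv(report$peptide_hits, file.path(out_dir, "peptide_hits.tsv"))
  write_tsv(report$frameshifts, file.path(out_dir, "frameshifts.tsv"))
  write_tsv(report$filtered_hits, file.path(out_dir, "filtered_hits.tsv"))
  write_tsv(report$curve$curves, file.path(out_dir, "annotation_curve.tsv"))
  write_tsv(report$specificity, file.path(out_dir, "specificity.tsv"))
  write_tsv(report$crosstab, file.path(out_dir, "crosstab.tsv"))
  if (!is.null(report$coding_excess))
    write_tsv(report$coding_excess, file.path(out_dir, "coding_excess.tsv"))
  if (!is.null(report$ortholog_pairs))
    write_tsv(report$ortholog_pairs, file.path(out_dir, "ortholog_pairs.tsv"))
  summary <- list(stats = report$stats, validation = report$validation[1:3],
                  fdr = report$fdr, manifest = report$manifest)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Generate synthetic inputs, run the pipeline and score against truth
#'
#' Convenience wrapper for testing and calibration: builds a synthetic
#' transcriptome with [generate_transcriptome()], digests and samples
#' peptides, generates hit and orthologue tables, runs [run_pipeline()]
#' and evaluates the result against the generator's ground truth.
#'
#' @param syn_config A [synthetic_config()].
#' @param config A [pipeline_config()].
#' @param patterns Optional PROSITE-syntax patterns (see [run_pipeline()]).
#' @param out_dir Optional output directory.
#' @return List with `report` (the [run_pipeline()] result), `truth`,
#'   `peptide_table`, `ortholog_truth` and `evaluation`, where
#'   `evaluation` holds `peptide_recall`, `frameshift` (per-transcript
#'   calls vs implanted counts on transcripts with full segment coverage)
#'   and `specificity` (precision/recall of the candidate set).
#' @export
run_synthetic_pipeline <- function(syn_config = synthetic_config(),
                                   config = pipeline_config(),
                                   patterns = NULL, out_dir = NULL) {
  gen <- generate_transcriptome(syn_config)
  pep_table <- digest_and_sample_peptides(gen$truth, syn_config)
  hit_gen <- generate_hit_tables(gen$truth, syn_config)
  orth <- generate_ortholog_tables(gen$truth, syn_config)

  report <- run_pipeline(gen$transcripts,
                         observed_peptides(pep_table),
                         hit_gen$tables, go_map = hit_gen$go_map,
                         orthologs = orth, patterns = patterns,
                         config = config, out_dir = out_dir)
  evaluation <- evaluate_against_truth(report, gen$truth, pep_table,
                                       orth$truth,
                                       min_peptides = config$min_peptides)
  list(report = report, truth = gen$truth, peptide_table = pep_table,
       ortholog_truth = orth$truth, evaluation = evaluation)
}

#' Score a pipeline report against synthetic ground truth
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param truth Truth table from [generate_transcriptome()].
#' @param peptide_table Output of [digest_and_sample_peptides()].
#' @param ortholog_truth Optional planted orthologue truth.
#' @param min_peptides Peptide-verification threshold used in the run.
#' @return List with components `peptide_recall`, `frameshift`,
#'   `specificity`, and (when orthologue truth is given) `orthologs`.
#' @export
evaluate_against_truth <- function(report, truth, peptide_table,
                                   ortholog_truth = NULL,
                                   min_peptides = 1L) {
  hits <- report$peptide_hits
  obs <- peptide_table[peptide_table$observed, , drop = FALSE]

  ## peptide recall: every observed peptide recovered on its source
  ## transcript (comparison after I/L collapse)
  hit_key <- unique(paste(.collapse_il(hits$peptide), hits$transcript_id))
  obs_key <- unique(paste(.collapse_il(obs$peptide), obs$transcript_id))
  peptide_recall <- if (length(obs_key) == 0L) NA_real_ else
    mean(obs_key %in% hit_key)

  ## frameshift calls vs implanted indels, on transcripts where every
  ## inter-indel segment received at least one observed peptide
  fs_truth <- truth[truth$is_frameshifted, , drop = FALSE]
  fs <- report$frameshifts
  called <- stats::setNames(fs$n_shifts, fs$transcript_id)
  fs_rows <- lapply(seq_len(nrow(fs_truth)), function(i) {
    tid <- fs_truth$transcript_id[i]
    k <- length(fs_truth$frameshift_positions[[i]])
    segs <- obs$segment[obs$transcript_id == tid]
    covered <- length(unique(segs)) == k + 1L
    n_called <- if (tid %in% names(called)) unname(called[tid]) else 0L
    data.frame(transcript_id = tid, n_indels = k, n_called = n_called,
               fully_covered = covered, stringsAsFactors = FALSE)
  })
  fs_eval <- do.call(rbind, fs_rows)
  if (is.null(fs_eval))
    fs_eval <- data.frame(transcript_id = character(), n_indels = integer(),
                          n_called = integer(), fully_covered = logical(),
                          stringsAsFactors = FALSE)
  cov <- fs_eval[fs_eval$fully_covered, , drop = FALSE]
  frameshift <- list(
    per_transcript = fs_eval,
    n_fully_covered = nrow(cov),
    detection_rate = if (nrow(cov) > 0L) mean(cov$n_called == cov$n_indels)
                     else NA_real_,
    n_overcalled = sum(fs_eval$n_called > fs_eval$n_indels, na.rm = TRUE))

  ## specificity: candidate set vs truth-derived candidate set
  obs_counts <- table(unique(obs[, c("transcript_id", "peptide")])$transcript_id)
  verified_truth <- names(obs_counts)[obs_counts >= min_peptides]
  truth_cand <- truth$transcript_id[
    truth$specificity_class %in% c("no_hit", "urodele_only") &
      truth$transcript_id %in% verified_truth]
  called_cand <- report$specificity$transcript_id[report$specificity$candidate]
  tp <- length(intersect(called_cand, truth_cand))
  specificity <- list(
    n_truth = length(truth_cand), n_called = length(called_cand),
    precision = if (length(called_cand) > 0L) tp / length(called_cand) else NA_real_,
    recall = if (length(truth_cand) > 0L) tp / length(truth_cand) else NA_real_)

  out <- list(peptide_recall = peptide_recall, frameshift = frameshift,
              specificity = specificity)
  if (!is.null(ortholog_truth) && !is.null(report$ortholog_pairs)) {
    pairs <- report$ortholog_pairs
    key_called <- paste(pairs$query_id, pairs$subject_id)
    key_truth <- paste(ortholog_truth$query_id, ortholog_truth$subject_id)
    out$orthologs <- list(
      pairs_recovered = mean(key_truth %in% key_called),
      full_length_agree = {
        m <- match(key_truth, key_called)
        mean(pairs$full_length[m[!is.na(m)]] ==
               ortholog_truth$full_length[!is.na(m)])
      })
  }
  out
}
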