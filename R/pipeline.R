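#' Configuration for an end-to-end simulated bsRNA-seq run
#'
#' Bundles the generator, mapper and calling parameters of a two-condition,
#' two-replicate experiment with a planted cluster of consecutive
#' methylated cytosines (restored in condition B, absent in condition A)
#' over a background of equally methylated sites.
#'
#' @param n_transcripts,transcript_length,gc_fraction,n_spikeins see
#'   [make_transcriptome()].
#' @param cluster_m per-condition methylation of the planted cluster
#'   (default c(0, 0.8): unmethylated in A, methylated in B).
#' @param cluster_size number of consecutive C sites in the cluster.
#' @param n_background_sites equally methylated background sites.
#' @param background_m their methylation level in both conditions.
#' @param conditions condition labels.
#' @param sim a [sim_config()].
#' @param k,max_mismatch_fraction mapper parameters.
#' @param thresholds a [filter_thresholds()].
#' @param alpha,min_delta differential significance rule.
#' @param spikein_threshold spike-in conversion QC floor.
#' @param seed master seed (overrides `sim$seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_transcripts = 6L, transcript_length = 600L,
                            gc_fraction = 0.5, n_spikeins = 2L,
                            cluster_m = c(0, 0.8), cluster_size = 3L,
                            n_background_sites = 10L, background_m = 0.3,
                            conditions = c("EV", "NSUN7"),
                            sim = sim_config(), k = 20L,
                            max_mismatch_fraction = 0.05,
                            thresholds = filter_thresholds(),
                            alpha = 0.01, min_delta = 0.1,
                            spikein_threshold = 0.99, seed = 1L) {
  sim$seed <- as.integer(seed)
  structure(list(n_transcripts = n_transcripts,
                 transcript_length = transcript_length,
                 gc_fraction = gc_fraction, n_spikeins = n_spikeins,
                 cluster_m = cluster_m, cluster_size = cluster_size,
                 n_background_sites = n_background_sites,
                 background_m = background_m, conditions = conditions,
                 sim = sim, k = k,
                 max_mismatch_fraction = max_mismatch_fraction,
                 thresholds = thresholds, alpha = alpha,
                 min_delta = min_delta,
                 spikein_threshold = spikein_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the simulate-map-quantify-call-test pipeline
#'
#' Executes the stages in dependency order: simulate the reference, truth
#' map and bisulfite reads for every condition and replicate; map reads
#' against the collapsed reference; build per-replicate pileups; check
#' spike-in conversion; call candidate sites per condition; test
#' differential methylation between the two conditions; rank. When
#' `out_dir` is given, every stage hand-off is written as plain TSV/FASTA/
#' FASTQ and a JSON run manifest records the configuration, seed, per-file
#' MD5 checksums, spike-in QC verdicts and warnings. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list: `transcripts`, `truth`, `reads` (nested by condition and
#'   replicate), `mapping_summary`, `pileups`, `spikein_qc`, `calls` (per
#'   condition), `diff` (ranked differential table), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  conds <- config$conditions
  stopifnot(length(conds) == 2L)

  transcripts <- make_transcriptome(config$n_transcripts,
                                    config$transcript_length,
                                    config$gc_fraction, config$n_spikeins,
                                    seed = config$seed)
  truth <- assign_truth(transcripts,
                        n_random = config$n_background_sites,
                        m_random = rep(config$background_m, 2L),
                        cluster = if (config$cluster_size > 0L)
                          list(m = config$cluster_m, size = config$cluster_size,
                               margin = config$sim$read_length),
                        conditions = conds, seed = config$seed)
  index <- index_reference(transcripts, k = config$k)

  reads <- list()
  pileups <- list()
  map_summary <- list()
  for (cond in conds) {
    reads[[cond]] <- list()
    pl <- list()
    for (rep_i in seq_len(config$sim$n_replicates)) {
      rd <- withCallingHandlers(
        bisulfite_reads(transcripts, truth, config$sim, cond, rep_i),
        warning = log_warning)
      reads[[cond]][[rep_i]] <- rd
      mp <- map_all(rd, index, config$max_mismatch_fraction)
      map_summary[[paste0(cond, ":rep", rep_i)]] <- mp$summary
      pl[[rep_i]] <- build_pileup(mp$alignments, rd, transcripts,
                                  replicate = rep_i)
    }
    pileups[[cond]] <- do.call(rbind, pl)
  }

  spikein_qc <- do.call(rbind, lapply(conds, function(cond) {
    qc <- withCallingHandlers(
      spikein_conversion(pileups[[cond]], transcripts,
                         threshold = config$spikein_threshold),
      warning = log_warning)
    qc$condition <- cond
    qc
  }))

  calls <- lapply(pileups, call_sites, thresholds = config$thresholds,
                  replicates = seq_len(config$sim$n_replicates),
                  allow_any_replicates = config$sim$n_replicates != 2L)
  cand_union <- do.call(rbind, lapply(calls, function(cl)
    cl[cl$candidate, c("transcript_id", "pos"), drop = FALSE]))
  diff <- call_differential(pileups[[conds[1L]]], pileups[[conds[2L]]],
                            candidates = cand_union, alpha = config$alpha,
                            min_delta = config$min_delta)
  if (nrow(diff) > 0L) diff <- rank_top(diff)

  manifest <- list(tool = "bsm5c", version = "0.1.0", seed = config$seed,
                   conditions = conds,
                   config = config[setdiff(names(config), c("sim", "thresholds"))],
                   sim = unclass(config$sim),
                   thresholds = unclass(config$thresholds),
                   mapping_summary = map_summary,
                   spikein_qc = spikein_qc,
                   warnings = warnings_log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    put <- function(rel, writer) {
      path <- file.path(out_dir, rel)
      writer(path)
      files[length(files) + 1L] <<- rel
      files <<- files
    }
    put("reference.fa", function(p) write_transcripts_fasta(transcripts, p))
    put("truth.tsv", function(p) write_truth_tsv(truth, p))
    for (cond in conds) for (rep_i in seq_len(config$sim$n_replicates))
      put(sprintf("reads_%s_rep%d.fastq", cond, rep_i),
          function(p) write_reads_fastq(reads[[cond]][[rep_i]], p))
    for (cond in conds)
      put(sprintf("pileup_%s.tsv", cond),
          function(p) write_pileup_tsv(pileups[[cond]], p))
    for (cond in conds)
      put(sprintf("candidates_%s.tsv", cond), function(p)
        utils::write.table(calls[[cond]], p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    put("diff.tsv", function(p)
      utils::write.table(diff, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    manifest$files <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$files) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
  }

  list(transcripts = transcripts, truth = truth, reads = reads,
       mapping_summary = map_summary, pileups = pileups,
       spikein_qc = spikein_qc, calls = calls, diff = diff,
       manifest = manifest)
}

#' Verify the checksum closure of a pipeline run directory
#'
#' Recomputes the MD5 checksum of every file referenced by the run manifest
#' and errors naming the first missing or modified file.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return TRUE, invisibly.
#' @export
verify_manifest <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  for (rel in names(manifest$files)) {
    path <- file.path(out_dir, rel)
    if (!file.exists(path))
      stop(sprintf("manifest file missing: %s", rel), call. = FALSE)
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, manifest$files[[rel]]))
      stop(sprintf("checksum mismatch for %s", rel), call. = FALSE)
  }
  invisible(TRUE)
}
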