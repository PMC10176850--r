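#' Simulator configuration for bisulfite-converted reads
#'
#' Holds the forward-model parameters of the read simulator. `e` is the
#' bisulfite conversion efficiency: the probability that an *unmethylated*
#' cytosine is read as thymine. `overconversion` is the probability that a
#' *methylated* cytosine is nevertheless read as thymine (default 0).
#' `seq_error` is a uniform per-base substitution rate applied after
#' conversion.
#'
#' @param e conversion efficiency in `[0,1]`.
#' @param overconversion overconversion rate in `[0,1]`.
#' @param seq_error per-base substitution probability in `[0,1]`.
#' @param read_length read length in bases (>= 1).
#' @param mean_depth target fold-coverage (> 0).
#' @param n_replicates replicates per condition.
#' @param seed master integer seed.
#' @param depth_model `"tiling"` (fixed read count, uniform random starts;
#'   low-variance default) or `"poisson"` (Poisson-distributed read count).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(e = 0.995, overconversion = 0, seq_error = 0.001,
                       read_length = 75L, mean_depth = 60,
                       n_replicates = 2L, seed = 1L,
                       depth_model = c("tiling", "poisson")) {
  depth_model <- match.arg(depth_model)
  stopifnot(is_probability(e), is_probability(overconversion),
            is_probability(seq_error))
  if (read_length < 1L) stop("read_length must be >= 1", call. = FALSE)
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(e = e, overconversion = overconversion,
                 seq_error = seq_error, read_length = as.integer(read_length),
                 mean_depth = mean_depth, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), depth_model = depth_model),
            class = "sim_config")
}

#' Generate a synthetic transcript reference with spike-in controls
#'
#' Random transcript sequences over ACGT at a configurable GC fraction, plus
#' `n_spikeins` flagged spike-in transcripts. Spike-ins model the fully
#' unmethylated in vitro transcripts added before bisulfite conversion to
#' measure conversion efficiency; truth maps never place methylation on them.
#'
#' @param n_transcripts number of (non-spike-in) transcripts, >= 1.
#' @param length transcript length in bases.
#' @param gc_fraction fraction of G+C bases in `[0,1]`.
#' @param n_spikeins number of spike-in transcripts (>= 0).
#' @param seed integer seed; identical arguments and seed give identical
#'   sequences.
#' @param spikein_length length of spike-in transcripts (default `length`).
#' @return data.frame with columns `id`, `sequence`, `is_spikein`.
#' @export
make_transcriptome <- function(n_transcripts, length, gc_fraction = 0.5,
                               n_spikeins = 2L, seed = 1L,
                               spikein_length = length) {
  if (n_transcripts < 1L) stop("n_transcripts must be >= 1", call. = FALSE)
  if (length < 1L || spikein_length < 1L) stop("length must be >= 1", call. = FALSE)
  if (n_spikeins < 0L) stop("n_spikeins must be >= 0", call. = FALSE)
  stopifnot(is_probability(gc_fraction))
  set.seed(derive_seed(seed, "transcriptome"))
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  draw <- function(len) paste(sample(names(probs), len, replace = TRUE,
                                     prob = probs), collapse = "")
  ids <- c(sprintf("tx%02d", seq_len(n_transcripts)),
           if (n_spikeins > 0L) sprintf("spikein%d", seq_len(n_spikeins)))
  lens <- c(rep(length, n_transcripts), rep(spikein_length, n_spikeins))
  data.frame(id = ids,
             sequence = vapply(lens, draw, character(1L)),
             is_spikein = rep(c(FALSE, TRUE), c(n_transcripts, n_spikeins)),
             stringsAsFactors = FALSE)
}

#' Build a ground-truth methylation map
#'
#' Maps (transcript, 0-based cytosine position) to a per-condition latent
#' methylation probability. This is the simulator's contract with the tests:
#' the empirical non-conversion level estimates it. Sites can be planted
#' explicitly, at random, and as a cluster of consecutive cytosines
#' (modelling adjacent sites that share one methylation profile).
#'
#' @param transcripts data.frame from [make_transcriptome()].
#' @param sites optional explicit data.frame with columns `transcript_id`,
#'   `pos` (0-based) and one `m_<condition>` column per condition.
#' @param n_random number of additional random sites to place on
#'   non-spike-in cytosines.
#' @param m_random per-condition methylation levels for random sites (length
#'   = number of conditions, recycled).
#' @param cluster optional list `list(transcript_id =, m =, size = 3,
#'   margin = 0)` planting `size` sites on a run of consecutive Cs of that
#'   transcript (the first CCC.. run of at least `size` Cs starting at
#'   least `margin` bases from either transcript end — read coverage decays
#'   toward the ends, so generators targeting the coverage filters should
#'   set `margin` to the read length); `m` gives the per-condition levels.
#'   `transcript_id = NULL` picks the first non-spike-in transcript
#'   containing such a run.
#' @param conditions condition labels (default `c("EV", "NSUN7")`).
#' @param seed integer seed for random placement.
#' @return data.frame with columns `transcript_id`, `pos`, and one
#'   `m_<condition>` column per condition; attribute `"conditions"`.
#' @export
assign_truth <- function(transcripts, sites = NULL, n_random = 0L,
                         m_random = c(0.3, 0.3), cluster = NULL,
                         conditions = c("EV", "NSUN7"), seed = 1L) {
  mcols <- paste0("m_", conditions)
  empty <- as.data.frame(c(list(transcript_id = character(0), pos = integer(0)),
                           stats::setNames(rep(list(numeric(0)), length(mcols)), mcols)),
                         stringsAsFactors = FALSE)
  out <- list()

  check_site <- function(tx, pos) {
    row <- match(tx, transcripts$id)
    if (is.na(row)) stop(sprintf("unknown transcript '%s'", tx), call. = FALSE)
    if (transcripts$is_spikein[row])
      stop(sprintf("cannot place methylation on spike-in transcript '%s'", tx),
           call. = FALSE)
    base <- substr(transcripts$sequence[row], pos + 1L, pos + 1L)
    if (!identical(base, "C"))
      stop(sprintf("position %d of transcript '%s' is '%s', not a C",
                   pos, tx, base), call. = FALSE)
  }

  if (!is.null(sites)) {
    stopifnot(all(c("transcript_id", "pos", mcols) %in% names(sites)))
    for (i in seq_len(nrow(sites))) check_site(sites$transcript_id[i], sites$pos[i])
    out <- c(out, list(sites[, c("transcript_id", "pos", mcols)]))
  }

  if (!is.null(cluster)) {
    size <- if (is.null(cluster$size)) 3L else as.integer(cluster$size)
    margin <- if (is.null(cluster$margin)) 0L else as.integer(cluster$margin)
    cand <- if (is.null(cluster$transcript_id))
      transcripts$id[!transcripts$is_spikein] else cluster$transcript_id
    placed <- FALSE
    for (tx in cand) {
      seqc <- transcripts$sequence[match(tx, transcripts$id)]
      hits <- gregexpr(strrep("C", size), seqc, fixed = TRUE)[[1L]]
      hits <- hits[hits > 0L & hits - 1L >= margin &
                     hits - 1L + size <= nchar(seqc) - margin]
      if (length(hits) > 0L) {
        pos <- hits[1L] - 1L + seq_len(size) - 1L
        df <- data.frame(transcript_id = tx, pos = pos, stringsAsFactors = FALSE)
        for (j in seq_along(mcols)) df[[mcols[j]]] <- rep_len(cluster$m, length(mcols))[j]
        for (i in seq_len(nrow(df))) check_site(df$transcript_id[i], df$pos[i])
        out <- c(out, list(df))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("no run of %d consecutive Cs found for cluster placement", size),
           call. = FALSE)
  }

  if (n_random > 0L) {
    set.seed(derive_seed(seed, "truth:random"))
    pool <- do.call(rbind, lapply(which(!transcripts$is_spikein), function(r) {
      p <- char_positions0(transcripts$sequence[r])
      if (length(p) == 0L) return(NULL)
      data.frame(transcript_id = transcripts$id[r], pos = p,
                 stringsAsFactors = FALSE)
    }))
    taken <- if (length(out)) do.call(rbind, lapply(out, `[`, c("transcript_id", "pos")))
    if (!is.null(taken))
      pool <- pool[!paste(pool$transcript_id, pool$pos) %in%
                     paste(taken$transcript_id, taken$pos), ]
    if (nrow(pool) < n_random)
      stop("not enough free cytosine positions for random placement", call. = FALSE)
    pick <- pool[sort(sample.int(nrow(pool), n_random)), ]
    for (j in seq_along(mcols)) pick[[mcols[j]]] <- rep_len(m_random, length(mcols))[j]
    out <- c(out, list(pick))
  }

  truth <- if (length(out)) do.call(rbind, out) else empty
  rownames(truth) <- NULL
  stopifnot(is_probability(unlist(truth[mcols])) || nrow(truth) == 0L)
  if (anyDuplicated(paste(truth$transcript_id, truth$pos)))
    stop("duplicate truth positions", call. = FALSE)
  attr(truth, "conditions") <- conditions
  truth
}

#' Write / read a truth map as TSV
#'
#' @param truth data.frame from [assign_truth()].
#' @param path file path.
#' @return `path` (writer) or the truth data.frame (reader).
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  truth <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(truth, "conditions") <- sub("^m_", "", grep("^m_", names(truth), value = TRUE))
  truth
}

#' Simulate bisulfite-converted reads for one condition and replicate
#'
#' Forward model, per read molecule and reference cytosine it covers:
#' methylated ~ Bernoulli(m_true); a methylated C emits C with probability
#' `1 - overconversion`, else T; an unmethylated C emits T with probability
#' `e`, else C. Every emitted base is then substituted uniformly at random
#' with probability `seq_error`. Non-C reference bases are copied (up to
#' sequencing error). Reads are sense-strand only: RNA bisulfite chemistry
#' acts on the single-stranded molecule, so no reverse-complement strand is
#' simulated.
#'
#' Read count per transcript is `round(mean_depth * length / read_length)`
#' (`depth_model = "tiling"`; round-half-even) or Poisson with that mean;
#' start positions are uniform over the valid range. Transcripts shorter
#' than the read length are skipped with a warning. Read ids encode
#' provenance as `<transcript>:<start0>:<condition>:rep<k>:<serial>` for
#' test introspection.
#'
#' @param transcripts data.frame from [make_transcriptome()].
#' @param truth data.frame from [assign_truth()] (may have zero rows).
#' @param config a [sim_config()].
#' @param condition condition label; must match a `m_<condition>` truth column.
#' @param replicate replicate index in `1..n_replicates`.
#' @return data.frame with columns `read_id`, `sequence`, `transcript_id`,
#'   `start` (0-based); attributes `condition`, `replicate`.
#' @export
bisulfite_reads <- function(transcripts, truth, config, condition, replicate) {
  stopifnot(inherits(config, "sim_config"))
  if (replicate < 1L || replicate > config$n_replicates)
    stop("replicate index out of range", call. = FALSE)
  mcol <- paste0("m_", condition)
  if (nrow(truth) > 0L && !mcol %in% names(truth))
    stop(sprintf("truth has no column '%s'", mcol), call. = FALSE)
  set.seed(derive_seed(config$seed, paste0("reads:", condition, ":rep", replicate)))
  L <- config$read_length
  out <- vector("list", nrow(transcripts))
  serial <- 0L
  for (r in seq_len(nrow(transcripts))) {
    tx <- transcripts$id[r]
    seqc <- strsplit(transcripts$sequence[r], "", fixed = TRUE)[[1L]]
    tlen <- length(seqc)
    if (tlen < L) {
      warning(sprintf("transcript '%s' (length %d) shorter than read length %d; skipped",
                      tx, tlen, L), call. = FALSE)
      next
    }
    n_reads <- if (config$depth_model == "poisson")
      stats::rpois(1L, config$mean_depth * tlen / L)
    else as.integer(round(config$mean_depth * tlen / L))
    if (n_reads == 0L) next
    starts <- sample.int(tlen - L + 1L, n_reads, replace = TRUE) - 1L  # 0-based
    # per-position latent methylation level (0 outside truth map)
    mvec <- numeric(tlen)
    if (nrow(truth) > 0L) {
      tr <- truth[truth$transcript_id == tx, ]
      if (nrow(tr) > 0L) mvec[tr$pos + 1L] <- tr[[mcol]]
    }
    idx <- outer(starts, 0:(L - 1L), "+") + 1L       # n_reads x L, 1-based
    base <- matrix(seqc[idx], nrow = n_reads)
    isC <- base == "C"
    nC <- sum(isC)
    if (nC > 0L) {
      meth <- stats::runif(nC) < mvec[idx[isC]]
      emit <- character(nC)
      emit[meth] <- ifelse(stats::runif(sum(meth)) < config$overconversion, "T", "C")
      emit[!meth] <- ifelse(stats::runif(sum(!meth)) < config$e, "T", "C")
      base[isC] <- emit
    }
    if (config$seq_error > 0) {
      err <- stats::runif(length(base)) < config$seq_error
      if (any(err)) {
        alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
        pick <- ceiling(stats::runif(sum(err)) * 3)
        base[err] <- substring(alt[base[err]], pick, pick)
      }
    }
    seqs <- apply(base, 1L, paste, collapse = "")
    ids <- sprintf("%s:%d:%s:rep%d:%06d", tx, starts, condition, replicate,
                   serial + seq_len(n_reads))
    serial <- serial + n_reads
    out[[r]] <- data.frame(read_id = ids, sequence = seqs, transcript_id = tx,
                           start = starts, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(reads))
    reads <- data.frame(read_id = character(0), sequence = character(0),
                        transcript_id = character(0), start = integer(0),
                        stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  attr(reads, "condition") <- condition
  attr(reads, "replicate") <- replicate
  reads
}

#' Simulate a clone set from targeted bisulfite sequencing
#'
#' Each clone represents one original molecule. Per clone and reference
#' cytosine, methylation is drawn Bernoulli(m_true) before conversion; a
#' methylated C stays C, an unmethylated C converts to T with the clone's
#' conversion efficiency. `round(incomplete_fraction * n_clones)` clones are
#' simulated with degraded efficiency `e_bad` (ground-truth flagged),
#' modelling incomplete bisulfite conversion of structured molecules; the
#' rest use `e_good`.
#'
#' @param reference unconverted amplicon/region sequence (ACGT).
#' @param m_true methylation probabilities: a single number recycled over
#'   scored positions, or a named numeric vector keyed by 0-based scored
#'   position. Cytosines outside the scored set are unmethylated.
#' @param mode `"RNA-anyC"` (all Cs scored) or `"DNA-CpG"` (CpG-context Cs).
#' @param n_clones number of clones, >= 1.
#' @param incomplete_fraction fraction of clones with degraded conversion.
#' @param e_good,e_bad conversion efficiencies; must satisfy `e_bad < e_good`
#'   whenever any incomplete clone is requested.
#' @param seed integer seed.
#' @param region_id region identifier.
#' @return list of class `clone_set`: `region_id`, `reference`, `mode`,
#'   `clones` (named character vector), `scored_pos` (0-based),
#'   `truth_states` (clones x scored positions, "M"/"U"), `incomplete_flags`.
#' @export
clone_sequences <- function(reference, m_true = 0, mode = c("RNA-anyC", "DNA-CpG"),
                            n_clones = 12L, incomplete_fraction = 0,
                            e_good = 0.99, e_bad = 0.7, seed = 1L,
                            region_id = "region1") {
  mode <- match.arg(mode)
  if (n_clones < 1L) stop("n_clones must be >= 1", call. = FALSE)
  stopifnot(is_probability(incomplete_fraction), is_probability(e_good),
            is_probability(e_bad), is_probability(m_true))
  n_bad <- as.integer(round(incomplete_fraction * n_clones))
  if (n_bad > 0L && e_bad >= e_good)
    stop("e_bad must be < e_good", call. = FALSE)
  assert_alphabet(reference, what = "reference")
  scored <- find_scored_positions(reference, mode)
  allC <- char_positions0(reference)
  mvec <- stats::setNames(numeric(length(allC)), allC)
  if (length(scored) > 0L) {
    if (is.null(names(m_true))) {
      mvec[as.character(scored)] <- rep_len(m_true, length(scored))
    } else {
      bad <- setdiff(names(m_true), as.character(scored))
      if (length(bad) > 0L)
        stop(sprintf("m_true names %s are not scored positions",
                     paste(bad, collapse = ", ")), call. = FALSE)
      mvec[names(m_true)] <- m_true
    }
  }
  set.seed(derive_seed(seed, paste0("clones:", region_id)))
  flags <- rep(FALSE, n_clones)
  if (n_bad > 0L) flags[sample.int(n_clones, n_bad)] <- TRUE
  refchars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  clones <- character(n_clones)
  truth_states <- matrix(NA_character_, n_clones, length(scored),
                         dimnames = list(sprintf("clone%02d", seq_len(n_clones)),
                                         as.character(scored + 1L)))
  for (k in seq_len(n_clones)) {
    e <- if (flags[k]) e_bad else e_good
    chars <- refchars
    meth <- stats::runif(length(allC)) < mvec
    conv <- !meth & (stats::runif(length(allC)) < e)
    chars[allC + 1L][conv] <- "T"
    clones[k] <- paste(chars, collapse = "")
    if (length(scored) > 0L)
      truth_states[k, ] <- ifelse(meth[match(scored, allC)], "M", "U")
  }
  names(clones) <- rownames(truth_states)
  structure(list(region_id = region_id, reference = reference, mode = mode,
                 clones = clones, scored_pos = scored,
                 truth_states = truth_states, incomplete_flags = flags),
            class = "clone_set")
}

#' Simulate paired promoter-methylation / expression / clinical tables
#'
#' Two sample groups: "methylated" promoters draw high beta-values and low
#' expression, "unmethylated" the converse, with configurable separation.
#' Clinical covariates are drawn per stated category frequencies,
#' independent of methylation status by default.
#'
#' @param n_samples number of samples, >= 4.
#' @param effect list with elements `beta_meth`, `beta_unmeth`, `beta_sd`,
#'   `expr_meth`, `expr_unmeth`, `expr_sd`. A zero-effect specification sets
#'   the group means equal.
#' @param n_cpg number of promoter CpG probes per sample.
#' @param prop_methylated fraction of samples in the methylated group
#'   (default 0.414, the hypermethylation frequency in primary liver
#'   tumours).
#' @param clinical_freq named list of category-probability vectors for
#'   clinical covariates.
#' @param seed integer seed.
#' @return list: `samples` (sample_id, group, mean_beta, expression +
#'   clinical columns) and `beta` (per-CpG beta-values, samples x probes).
#' @export
simulate_assoc_tables <- function(n_samples,
                                  effect = list(beta_meth = 0.8, beta_unmeth = 0.1,
                                                beta_sd = 0.05,
                                                expr_meth = -1, expr_unmeth = 1,
                                                expr_sd = 0.5),
                                  n_cpg = 5L, prop_methylated = 0.414,
                                  clinical_freq = list(
                                    gender = c(male = 0.676, female = 0.324),
                                    age_group = c("le60" = 0.477, "gt60" = 0.523)),
                                  seed = 1L) {
  if (n_samples < 4L) stop("n_samples must be >= 4", call. = FALSE)
  set.seed(derive_seed(seed, "assoc"))
  grp <- ifelse(stats::runif(n_samples) < prop_methylated,
                "methylated", "unmethylated")
  mu_b <- ifelse(grp == "methylated", effect$beta_meth, effect$beta_unmeth)
  latent <- pmin(1, pmax(0, stats::rnorm(n_samples, mu_b, effect$beta_sd)))
  beta <- matrix(pmin(1, pmax(0, stats::rnorm(n_samples * n_cpg, rep(latent, n_cpg), 0.03))),
                 nrow = n_samples,
                 dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                                 sprintf("cg%02d", seq_len(n_cpg))))
  mean_beta <- apply(beta, 1L, summarize_promoter_beta)
  mu_e <- ifelse(grp == "methylated", effect$expr_meth, effect$expr_unmeth)
  expr <- stats::rnorm(n_samples, mu_e, effect$expr_sd)
  samples <- data.frame(sample_id = rownames(beta), group = grp,
                        mean_beta = mean_beta, expression = expr,
                        stringsAsFactors = FALSE)
  for (covar in names(clinical_freq)) {
    p <- clinical_freq[[covar]]
    samples[[covar]] <- sample(names(p), n_samples, replace = TRUE, prob = p)
  }
  list(samples = samples, beta = beta)
}
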