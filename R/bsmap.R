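#' Collapse a nucleotide sequence to the three-letter bisulfite alphabet
#'
#' Replaces every C by T, leaving all other symbols unchanged (length
#' preserved). Bisulfite reads are aligned in this collapsed space so that
#' conversion status (C vs T at a reference C) never counts as a mismatch.
#' Idempotent: collapsing a C-free sequence is the identity.
#'
#' @param sequence character vector of sequences over ACGTN.
#' @return collapsed sequences.
#' @export
collapse_sequence <- function(sequence) {
  for (s in sequence) assert_alphabet(s, c("A", "C", "G", "T", "N"))
  chartr("C", "T", sequence)
}

#' Build a collapsed k-mer seed index over a transcript reference
#'
#' Indexes every k-mer of every C-to-T collapsed transcript with its
#' (transcript, 0-based offset). Transcripts shorter than `k` are excluded
#' with a warning.
#'
#' @param transcripts data.frame with columns `id`, `sequence`.
#' @param k seed length in bases, >= 8.
#' @return list of class `collapsed_index`: `k`, `seeds` (data.table keyed
#'   by kmer: kmer, tx, offset0), `collapsed` (named collapsed sequences),
#'   `lengths` (named transcript lengths).
#' @export
index_reference <- function(transcripts, k = 20L) {
  if (k < 8L) stop("k must be >= 8", call. = FALSE)
  k <- as.integer(k)
  lens <- nchar(transcripts$sequence)
  short <- lens < k
  if (any(short))
    warning(sprintf("%d transcript(s) shorter than k=%d excluded from index: %s",
                    sum(short), k, paste(transcripts$id[short], collapse = ", ")),
            call. = FALSE)
  keep <- transcripts[!short, , drop = FALSE]
  collapsed <- stats::setNames(collapse_sequence(keep$sequence), keep$id)
  seeds <- if (nrow(keep) > 0L) {
    data.table::rbindlist(lapply(seq_len(nrow(keep)), function(r) {
      L <- nchar(collapsed[r])
      start <- seq_len(L - k + 1L)
      data.table::data.table(kmer = substring(collapsed[r], start, start + k - 1L),
                             tx = keep$id[r], offset0 = start - 1L)
    }))
  } else {
    data.table::data.table(kmer = character(0), tx = character(0),
                           offset0 = integer(0))
  }
  data.table::setkey(seeds, kmer)
  structure(list(k = k, seeds = seeds, collapsed = collapsed,
                 lengths = stats::setNames(nchar(collapsed), names(collapsed))),
            class = "collapsed_index")
}

# Count mismatches between two equal-length strings (byte comparison).
.str_mismatches <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Map one read against a collapsed index
#'
#' Candidate loci come from exact collapsed-seed hits of the first k-mer and
#' a mid-read k-mer; each candidate is scored by full-length ungapped
#' comparison in collapsed space. The read is `unique` iff exactly one locus
#' attains the minimal mismatch count and that count is at most
#' `floor(max_mismatch_fraction * read length)`; ties give `ambiguous`; no
#' candidate within the threshold gives `unmapped`.
#'
#' @param read read sequence (original, uncollapsed).
#' @param index a [index_reference()] result.
#' @param max_mismatch_fraction maximum mismatch fraction in `[0,1]`.
#' @param read_id identifier carried into the result.
#' @return one-row data.frame: `read_id`, `transcript_id`, `start`
#'   (0-based; NA unless unique), `mismatches`, `status`.
#' @export
map_read <- function(read, index, max_mismatch_fraction = 0.05,
                     read_id = "read1") {
  res <- map_all(data.frame(read_id = read_id, sequence = read,
                            stringsAsFactors = FALSE),
                 index, max_mismatch_fraction)
  res$alignments
}

#' Map a read set against a collapsed index
#'
#' Vectorized batch version of [map_read()]; results are order-independent
#' per read.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param index a [index_reference()] result.
#' @param max_mismatch_fraction maximum mismatch fraction in `[0,1]`.
#' @return list: `alignments` (read_id, transcript_id, start, mismatches,
#'   status) and `summary` (unique/ambiguous/unmapped counts, summing to the
#'   number of reads).
#' @export
map_all <- function(reads, index, max_mismatch_fraction = 0.05) {
  stopifnot(inherits(index, "collapsed_index"),
            is_probability(max_mismatch_fraction))
  n <- nrow(reads)
  empty <- data.frame(read_id = character(0), transcript_id = character(0),
                      start = integer(0), mismatches = integer(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(alignments = empty,
                summary = c(unique = 0L, ambiguous = 0L, unmapped = 0L)))
  k <- index$k
  rl <- nchar(reads$sequence)
  if (any(rl < k)) stop("read length must be >= k", call. = FALSE)
  coll <- collapse_sequence(reads$sequence)
  mid <- pmax(0L, (rl - k) %/% 2L)   # 0-based offset of mid-read seed
  qdt <- data.table::data.table(
    ridx = rep(seq_len(n), 2L),
    soff = c(rep(0L, n), mid),
    kmer = c(substring(coll, 1L, k), substring(coll, mid + 1L, mid + k)))
  hits <- index$seeds[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  status <- rep("unmapped", n)
  best_tx <- rep(NA_character_, n)
  best_start <- rep(NA_integer_, n)
  best_mm <- rep(NA_integer_, n)
  if (nrow(hits) > 0L) {
    hits[, start := offset0 - soff]
    hits <- unique(hits[, list(ridx, tx, start)])
    hits <- hits[start >= 0L & start + rl[ridx] <= index$lengths[tx]]
    if (nrow(hits) > 0L) {
      refsub <- substring(index$collapsed[hits$tx], hits$start + 1L,
                          hits$start + rl[hits$ridx])
      rdsub <- coll[hits$ridx]
      hits[, mm := mapply(.str_mismatches, rdsub, refsub, USE.NAMES = FALSE)]
      hits <- hits[mm <= floor(max_mismatch_fraction * rl[ridx])]
      if (nrow(hits) > 0L) {
        data.table::setorder(hits, ridx, mm, tx, start)
        agg <- hits[, list(tx = tx[1L], start = start[1L], mm = mm[1L],
                           tied = sum(mm == mm[1L]) > 1L), by = "ridx"]
        status[agg$ridx] <- ifelse(agg$tied, "ambiguous", "unique")
        ok <- !agg$tied
        best_tx[agg$ridx[ok]] <- agg$tx[ok]
        best_start[agg$ridx[ok]] <- agg$start[ok]
        best_mm[agg$ridx] <- agg$mm
      }
    }
  }
  aln <- data.frame(read_id = reads$read_id, transcript_id = best_tx,
                    start = best_start, mismatches = best_mm,
                    status = status, stringsAsFactors = FALSE)
  list(alignments = aln,
       summary = c(unique = sum(status == "unique"),
                   ambiguous = sum(status == "ambiguous"),
                   unmapped = sum(status == "unmapped")))
}

#' Write an alignment table as TSV
#'
#' @param alignments alignment data.frame from [map_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
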