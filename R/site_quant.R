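#' Build per-cytosine pileups from unique alignments
#'
#' For every reference cytosine covered by at least one uniquely mapped
#' read, counts reads showing C, T, or another base at that position. The
#' read base is taken from the original (uncollapsed) read at the aligned
#' offset, so the collapsed-space alignment never erases conversion status.
#'
#' @param alignments alignment table ([map_all()]); only rows with
#'   `status == "unique"` are used.
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param transcripts data.frame with columns `id`, `sequence`.
#' @param replicate replicate index recorded in the output.
#' @return data.frame (one row per covered reference C): `transcript_id`,
#'   `pos` (0-based), `pos_1based`, `replicate`, `c`, `t`, `other`,
#'   `coverage`, `m` (non-conversion level, NA when c + t = 0).
#' @export
build_pileup <- function(alignments, reads, transcripts, replicate = 1L) {
  aln <- alignments[alignments$status == "unique", , drop = FALSE]
  empty <- data.frame(transcript_id = character(0), pos = integer(0),
                      pos_1based = integer(0), replicate = integer(0),
                      c = integer(0), t = integer(0), other = integer(0),
                      coverage = integer(0), m = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) return(empty)
  ridx <- match(aln$read_id, reads$read_id)
  if (anyNA(ridx)) stop("alignment references unknown read id", call. = FALSE)
  if (anyNA(match(aln$transcript_id, transcripts$id)))
    stop("alignment references unknown transcript id", call. = FALSE)
  rl <- nchar(reads$sequence[ridx])
  parts <- list()
  for (tx in unique(aln$transcript_id)) {
    cpos <- char_positions0(transcripts$sequence[match(tx, transcripts$id)])
    if (length(cpos) == 0L) next
    sel <- which(aln$transcript_id == tx)
    starts <- aln$start[sel]
    ends <- starts + rl[sel] - 1L
    # covered C indices per alignment via findInterval on the sorted C list
    lo <- findInterval(starts - 0.5, cpos) + 1L
    hi <- findInterval(ends, cpos)
    nn <- pmax(0L, hi - lo + 1L)
    if (sum(nn) == 0L) next
    ai <- rep(sel[nn > 0L], nn[nn > 0L])
    ci <- unlist(lapply(which(nn > 0L), function(i) cpos[lo[i]:hi[i]]),
                 use.names = FALSE)
    off <- ci - aln$start[ai]                       # 0-based offset in read
    base <- substring(reads$sequence[ridx[ai]], off + 1L, off + 1L)
    parts[[tx]] <- data.table::data.table(transcript_id = tx, pos = ci,
                                          base = base)
  }
  if (length(parts) == 0L) return(empty)
  dt <- data.table::rbindlist(parts)
  pu <- dt[, list(c = sum(base == "C"), t = sum(base == "T"),
                  other = sum(!base %in% c("C", "T")), coverage = .N),
           by = c("transcript_id", "pos")]
  data.table::setorder(pu, transcript_id, pos)
  pu[, pos_1based := pos + 1L]
  pu[, replicate := as.integer(replicate)]
  pu[, m := ifelse(c + t > 0L, c / (c + t), NA_real_)]
  as.data.frame(pu[, list(transcript_id, pos, pos_1based, replicate,
                          c, t, other, coverage, m)])
}

#' Non-conversion level of a pileup site
#'
#' The empirical methylation estimate `m = c / (c + t)`: the fraction of
#' reads showing C among reads showing C or T. Bases other than C/T are
#' excluded from the denominator (they are sequencing noise, guarded
#' separately by the 80CT filter); `c + t = 0` yields NA (the site cannot
#' enter calling).
#'
#' @param c_count,t_count read counts showing C and T.
#' @return fraction in `[0,1]`, or NA.
#' @export
nonconversion_level <- function(c_count, t_count) {
  ifelse(c_count + t_count > 0, c_count / (c_count + t_count), NA_real_)
}

#' Spike-in bisulfite conversion efficiency
#'
#' Pools all cytosine sites of the spike-in transcripts (fully unmethylated
#' in vitro transcripts) per replicate: efficiency = sum(t) / (sum(c) +
#' sum(t)). Replicates whose efficiency falls below `threshold` fail QC;
#' the pipeline warns and annotates rather than aborting. With no covered
#' spike-in site the status is `"unavailable"`.
#'
#' @param pileup pileup table ([build_pileup()]), possibly several
#'   replicates bound together.
#' @param transcripts transcript table with `id`, `is_spikein`.
#' @param threshold minimum acceptable efficiency (default 0.99).
#' @return data.frame: `replicate`, `efficiency`, `pass`, `status`.
#' @export
spikein_conversion <- function(pileup, transcripts, threshold = 0.99) {
  spike <- transcripts$id[transcripts$is_spikein]
  reps <- sort(unique(pileup$replicate))
  if (length(reps) == 0L) reps <- 1L
  rows <- lapply(reps, function(r) {
    sub <- pileup[pileup$replicate == r & pileup$transcript_id %in% spike, ]
    ct <- sum(sub$c) + sum(sub$t)
    if (nrow(sub) == 0L || ct == 0L)
      return(data.frame(replicate = r, efficiency = NA_real_, pass = NA,
                        status = "unavailable", stringsAsFactors = FALSE))
    eff <- sum(sub$t) / ct
    data.frame(replicate = r, efficiency = eff, pass = eff >= threshold,
               status = if (eff >= threshold) "pass" else "fail",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$status == "fail"))
    warning(sprintf("spike-in conversion efficiency below %.3f in replicate(s) %s",
                    threshold,
                    paste(out$replicate[out$status == "fail"], collapse = ", ")),
            call. = FALSE)
  out
}

#' Write a pileup table as TSV
#'
#' @param pileup pileup data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
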