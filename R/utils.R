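#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Generators in this package never share a raw seed across independent
#' random streams (conditions, replicates, clone sets). Each stream seeds
#' its own RNG with `derive_seed(master, label)` so that replicates are
#' independent draws yet fully reproducible from one master seed.
#'
#' The splitting rule is a fixed affine hash of the label folded into the
#' master seed, reduced modulo 2^31 - 1 (R integers are 32-bit):
#' `(master + sum_i 31^(i-1) * byte_i) mod (2^31 - 1)`, accumulated in
#' double precision with interleaved reduction.
#'
#' @param master integer master seed.
#' @param stream character label of the stream (e.g. "reads:EV:rep1").
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, stream) {
  stopifnot(length(master) == 1L, is.finite(master),
            is.character(stream), length(stream) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Validate a nucleotide string over a restricted alphabet; errors name the
# first offending position (1-based).
assert_alphabet <- function(x, alphabet = c("A", "C", "G", "T"), what = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("illegal symbol '%s' in %s at position %d",
                 chars[bad[1L]], what, bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' 0-based positions of a base within a sequence
#'
#' Convenience accessor used throughout for cytosine coordinates (the
#' package is 0-based internally; rendered labels are 1-based).
#'
#' @param sequence a single sequence string.
#' @param char the base to locate (default "C").
#' @return integer vector of 0-based positions.
#' @export
char_positions0 <- function(sequence, char = "C") {
  which(strsplit(sequence, "", fixed = TRUE)[[1L]] == char) - 1L
}

is_probability <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Write transcripts to a FASTA file
#'
#' @param transcripts data.frame with columns `id` and `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(transcripts$sequence)
  names(seqs) <- transcripts$id
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read transcripts from a FASTA file
#'
#' @param path FASTA file.
#' @param spikein_pattern regular expression identifying spike-in ids.
#' @return data.frame with columns `id`, `sequence`, `is_spikein`.
#' @export
read_transcripts_fasta <- function(path, spikein_pattern = "^spikein") {
  seqs <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(seqs),
             sequence = as.character(seqs),
             is_spikein = grepl(spikein_pattern, names(seqs)),
             stringsAsFactors = FALSE)
}

#' Write a read set to FASTQ (4-line records, constant 'I' qualities)
#'
#' @param reads data.frame with columns `read_id` and `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  n <- nrow(reads)
  lines <- character(4L * n)
  if (n > 0L) {
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
    lines[seq(2L, by = 4L, length.out = n)] <- reads$sequence
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <-
      strrep("I", nchar(reads$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file.
#' @return data.frame with columns `read_id`, `sequence`.
#' @export
read_reads_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(seqs), sequence = as.character(seqs),
             stringsAsFactors = FALSE)
}
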