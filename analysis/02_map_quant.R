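#!/usr/bin/env Rscript
# Stage 2: conversion-aware mapping and per-cytosine quantification.
#
# Reads the FASTA/FASTQ hand-offs from stage 1, maps each replicate
# against the C-to-T collapsed reference (unique alignments only), builds
# per-cytosine pileups and checks the spike-in conversion efficiency.

suppressPackageStartupMessages(library(bsm5c))

ind <- "results/data"
out <- "results/pileups"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

transcripts <- read_transcripts_fasta(file.path(ind, "reference.fa"))
index <- index_reference(transcripts, k = 20)

for (cond in c("EV", "NSUN7")) {
  pl <- list()
  for (rep_i in 1:2) {
    rd <- read_reads_fastq(file.path(ind, sprintf("reads_%s_rep%d.fastq",
                                                  cond, rep_i)))
    mp <- map_all(rd, index, max_mismatch_fraction = 0.05)
    message(sprintf("%s rep%d: %d unique / %d ambiguous / %d unmapped",
                    cond, rep_i, mp$summary["unique"],
                    mp$summary["ambiguous"], mp$summary["unmapped"]))
    write_alignments_tsv(mp$alignments,
                         file.path(out, sprintf("aln_%s_rep%d.tsv", cond, rep_i)))
    pl[[rep_i]] <- build_pileup(mp$alignments, rd, transcripts, replicate = rep_i)
  }
  pileup <- do.call(rbind, pl)
  write_pileup_tsv(pileup, file.path(out, sprintf("pileup_%s.tsv", cond)))
  qc <- spikein_conversion(pileup, transcripts, threshold = 0.99)
  for (i in seq_len(nrow(qc)))
    message(sprintf("%s rep%d spike-in conversion: %.4f (%s)", cond,
                    qc$replicate[i], qc$efficiency[i], qc$status[i]))
  utils::write.table(qc, file.path(out, sprintf("spikein_qc_%s.tsv", cond)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
message("stage 2 outputs written to ", out)
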