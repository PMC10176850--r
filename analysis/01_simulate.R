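#!/usr/bin/env Rscript
# Stage 1: simulate the study's sequencing inputs.
#
# Two conditions (EV vs methyltransferase-restored), two biological
# replicates each, 60x depth at conversion efficiency 0.995, with two
# fully unmethylated spike-in transcripts and a planted cluster of three
# consecutive cytosines (unmethylated in EV, 0.8 in the restored
# condition) over an equally methylated background — plus targeted clone
# sets for the RNA amplicon and a promoter CpG island.

suppressPackageStartupMessages(library(bsm5c))

seed <- 20260923L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(e = 0.995, seq_error = 0.001, mean_depth = 60,
                  read_length = 75L, n_replicates = 2L, seed = seed)
transcripts <- make_transcriptome(6, 600, gc_fraction = 0.5, n_spikeins = 2,
                                  seed = seed)
truth <- assign_truth(transcripts, n_random = 10, m_random = c(0.3, 0.3),
                      cluster = list(m = c(0, 0.8), size = 3,
                                     margin = cfg$read_length),
                      seed = seed)
write_transcripts_fasta(transcripts, file.path(out, "reference.fa"))
write_truth_tsv(truth, file.path(out, "truth.tsv"))

for (cond in c("EV", "NSUN7")) {
  for (rep_i in 1:2) {
    rd <- bisulfite_reads(transcripts, truth, cfg, cond, rep_i)
    write_reads_fastq(rd, file.path(out, sprintf("reads_%s_rep%d.fastq",
                                                 cond, rep_i)))
    message(sprintf("%s rep%d: %d reads", cond, rep_i, nrow(rd)))
  }
}

cl <- truth[truth$m_NSUN7 > truth$m_EV, ]
message(sprintf("planted cluster: %s positions %s (1-based %s)",
                cl$transcript_id[1], paste(cl$pos, collapse = ","),
                paste(cl$pos + 1, collapse = ",")))

# RNA amplicon clone sets for both conditions (the amplicon spans the
# cluster region of the target transcript)
amp_tx <- cl$transcript_id[1]
amp_lo <- max(0, min(cl$pos) - 80)
amp_hi <- min(nchar(transcripts$sequence[transcripts$id == amp_tx]),
              max(cl$pos) + 80)
amplicon <- substr(transcripts$sequence[transcripts$id == amp_tx],
                   amp_lo + 1, amp_hi)
sc <- find_scored_positions(amplicon, "RNA-anyC")
m_ev <- setNames(rep(0, length(sc)), sc)
m_res <- m_ev
m_res[as.character(cl$pos - amp_lo)] <- 0.8
for (cond in c("EV", "NSUN7")) {
  cs <- clone_sequences(amplicon, m_true = if (cond == "EV") m_ev else m_res,
                        mode = "RNA-anyC", n_clones = 12,
                        incomplete_fraction = 1 / 12, e_good = 0.99,
                        e_bad = 0.7, seed = seed,
                        region_id = paste0("rna_amplicon_", cond))
  writeLines(paste0(">", names(cs$clones), "\n", cs$clones),
             file.path(out, sprintf("clones_rna_%s.fa", cond)))
}
writeLines(c(">rna_amplicon", amplicon), file.path(out, "rna_amplicon.fa"))

# DNA promoter CpG island clones: hypermethylated vs unmethylated line
set.seed(derive_seed(seed, "promoter"))
promoter <- paste(sample(c("A", "C", "G", "T"), 220, TRUE,
                         prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
writeLines(c(">promoter_island", promoter), file.path(out, "promoter_island.fa"))
for (status in c("methylated", "unmethylated")) {
  cs <- clone_sequences(promoter, m_true = if (status == "methylated") 0.9 else 0.05,
                        mode = "DNA-CpG", n_clones = 10,
                        incomplete_fraction = 0, e_good = 0.99, seed = seed,
                        region_id = paste0("promoter_", status))
  writeLines(paste0(">", names(cs$clones), "\n", cs$clones),
             file.path(out, sprintf("clones_dna_%s.fa", status)))
}
message("stage 1 outputs written to ", out)
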