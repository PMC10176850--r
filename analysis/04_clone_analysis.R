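#!/usr/bin/env Rscript
# Stage 4: targeted clone-based bisulfite sequencing analysis.
#
# RNA mode: clones of the amplicon spanning the planted cluster, EV vs
# restored condition, with the incomplete-conversion clone filter.
# DNA mode: promoter CpG island clones of a hypermethylated vs an
# unmethylated sample, with non-CpG conversion QC.

suppressPackageStartupMessages(library(bsm5c))

ind <- "results/data"
out <- "results/clones"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_fa <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

report <- function(label, clones, reference, mode) {
  cm <- suppressWarnings(analyze_clones(clones, reference, mode,
                                        region_id = label))
  s <- summarize_clones(cm)
  discarded <- names(cm$verdicts)[cm$verdicts != "kept"]
  message(sprintf("%s: %d/%d clones kept%s", label, cm$n_kept,
                  length(cm$verdicts),
                  if (length(discarded))
                    paste0(" (discarded: ", paste(discarded, collapse = ", "), ")")
                  else ""))
  utils::write.table(s$table, file.path(out, paste0(label, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("# %s (%s): %% methylated per scored position", label, mode),
               sprintf("# positions (1-based): %s",
                       paste(cm$labels, collapse = " ")),
               s$lollipop),
             file.path(out, paste0(label, "_lollipop.txt")))
  invisible(cm)
}

amplicon <- read_fa(file.path(ind, "rna_amplicon.fa"))[[1]]
for (cond in c("EV", "NSUN7")) {
  cm <- report(paste0("rna_", cond),
               read_fa(file.path(ind, sprintf("clones_rna_%s.fa", cond))),
               amplicon, "RNA-anyC")
  hot <- cm$percent[cm$percent >= 50 & !is.na(cm$percent)]
  if (length(hot))
    message(sprintf("  %s: methylated positions (>=50%%): C%s", cond,
                    paste(names(hot), collapse = ", C")))
}

promoter <- read_fa(file.path(ind, "promoter_island.fa"))[[1]]
for (status in c("methylated", "unmethylated")) {
  cm <- report(paste0("dna_", status),
               read_fa(file.path(ind, sprintf("clones_dna_%s.fa", status))),
               promoter, "DNA-CpG")
  message(sprintf("  promoter %s: mean CpG methylation %.1f%%", status,
                  mean(cm$percent, na.rm = TRUE)))
}
message("stage 4 outputs written to ", out)
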