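#!/usr/bin/env Rscript
# Stage 3: candidate m5C site calling and differential methylation.
#
# Applies the 30RC/5C/80CT/10MM filters (strict 7C single-replicate
# fallback) per condition, then tests the candidate union between
# conditions with pooled-count Fisher exact tests, BH correction, and the
# significance rule adjusted p < 0.01 with |delta| > 0.1.

suppressPackageStartupMessages(library(bsm5c))

ind <- "results/pileups"
out <- "results/differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

th <- filter_thresholds()   # 30RC, 5C (strict 7C), 80CT, 10MM
pileups <- lapply(c(EV = "EV", NSUN7 = "NSUN7"), function(cond)
  read_pileup_tsv(file.path(ind, sprintf("pileup_%s.tsv", cond))))

calls <- lapply(pileups, call_sites, thresholds = th)
for (cond in names(calls)) {
  sm <- candidate_summary(calls[[cond]])
  message(sprintf("%s: %d candidate sites (%d both-replicates, %d single-strict) of %d covered",
                  cond, sm$n_candidates, sm$by_mode["both-replicates"],
                  sm$by_mode["single-strict"], sm$n_sites))
  utils::write.table(calls[[cond]],
                     file.path(out, sprintf("candidates_%s.tsv", cond)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

cand_union <- do.call(rbind, lapply(calls, function(cl)
  cl[cl$candidate, c("transcript_id", "pos")]))
diff <- call_differential(pileups$EV, pileups$NSUN7, candidates = cand_union,
                          alpha = 0.01, min_delta = 0.1)
diff <- rank_top(diff)
utils::write.table(diff, file.path(out, "diff.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

sig <- diff[diff$significant, ]
message(sprintf("%d differentially methylated site(s):", nrow(sig)))
for (i in seq_len(nrow(sig)))
  message(sprintf("  %s C%d: m_EV = %.3f, m_NSUN7 = %.3f, delta = %+.3f, adj p = %.3g",
                  sig$transcript_id[i], sig$pos_1based[i], sig$m_a[i],
                  sig$m_b[i], sig$delta[i], sig$p_adj[i]))
message("stage 3 outputs written to ", out)
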