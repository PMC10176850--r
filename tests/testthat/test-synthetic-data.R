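test_that("transcriptome generator honors counts, determinism and composition bounds", {
  tx <- make_transcriptome(2, 500, 0.5, n_spikeins = 2, seed = 7)
  expect_equal(nrow(tx), 4)
  expect_equal(sum(tx$is_spikein), 2)
  expect_true(all(nchar(tx$sequence) == 500))

  tx2 <- make_transcriptome(2, 500, 0.5, n_spikeins = 2, seed = 7)
  expect_identical(tx, tx2)

  gc1 <- make_transcriptome(1, 200, gc_fraction = 1.0, n_spikeins = 0, seed = 1)
  expect_true(grepl("^[GC]+$", gc1$sequence))
  at0 <- make_transcriptome(1, 200, gc_fraction = 0.0, n_spikeins = 0, seed = 1)
  expect_true(grepl("^[AT]+$", at0$sequence))

  expect_error(make_transcriptome(0, 100), "n_transcripts")
  expect_error(make_transcriptome(2, 0), "length")
})

test_that("truth maps store planted sites, reject non-C and spike-in loci, and are seeded", {
  tx <- data.frame(id = c("tx1", "spikein1"),
                   sequence = c("AACCCGTACGTACCC", "ACGTACGTACGTACG"),
                   is_spikein = c(FALSE, TRUE))
  truth <- assign_truth(tx, sites = data.frame(transcript_id = "tx1", pos = 3,
                                               m_EV = 0.0, m_NSUN7 = 0.8))
  expect_equal(truth$m_EV[truth$pos == 3], 0.0)
  expect_equal(truth$m_NSUN7[truth$pos == 3], 0.8)

  expect_error(assign_truth(tx, sites = data.frame(transcript_id = "tx1", pos = 0,
                                                   m_EV = 0, m_NSUN7 = 1)),
               "not a C")
  expect_error(assign_truth(tx, sites = data.frame(transcript_id = "spikein1",
                                                   pos = 1, m_EV = 0, m_NSUN7 = 1)),
               "spike-in")

  big <- make_transcriptome(3, 400, seed = 11)
  r1 <- assign_truth(big, n_random = 10, m_random = c(0.2, 0.6), seed = 5)
  r2 <- assign_truth(big, n_random = 10, m_random = c(0.2, 0.6), seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10)

  cl <- assign_truth(tx, cluster = list(m = c(0, 0.8), size = 3))
  expect_equal(cl$pos, c(2, 3, 4))  # first CCC run of tx1
  expect_equal(cl$m_NSUN7, rep(0.8, 3))
})

test_that("read simulator limits: full conversion, full methylation, spike-in purity", {
  tx <- fixture_transcripts()
  cfg <- sim_config(e = 1.0, seq_error = 0, mean_depth = 20, seed = 3)
  truth0 <- assign_truth(tx, conditions = c("EV", "NSUN7"))

  rd <- bisulfite_reads(tx, truth0, cfg, "EV", 1)
  # e = 1, no methylation: every reference-C position reads T in every read
  for (i in seq_len(min(50, nrow(rd)))) {
    ref <- tx$sequence[tx$id == rd$transcript_id[i]]
    span <- substr(ref, rd$start[i] + 1, rd$start[i] + cfg$read_length)
    cpos <- which(strsplit(span, "")[[1]] == "C")
    got <- strsplit(rd$sequence[i], "")[[1]][cpos]
    expect_true(all(got == "T"))
  }
  # spike-in purity: no C at spike-in reference Cs
  sp <- rd[rd$transcript_id == "spikein1", ]
  expect_gt(nrow(sp), 0)
  expect_false(any(grepl("C", sp$sequence)))

  # fully methylated site reads C in every overlapping read
  cpos0 <- char_positions0(tx$sequence[1])[10]
  truth1 <- assign_truth(tx, sites = data.frame(transcript_id = tx$id[1],
                                                pos = cpos0, m_EV = 1, m_NSUN7 = 1))
  rd1 <- bisulfite_reads(tx, truth1, cfg, "EV", 1)
  over <- rd1[rd1$transcript_id == tx$id[1] &
                rd1$start <= cpos0 & rd1$start + cfg$read_length > cpos0, ]
  expect_gt(nrow(over), 10)
  expect_true(all(substr(over$sequence, cpos0 - over$start + 1,
                         cpos0 - over$start + 1) == "C"))
})

test_that("observed non-conversion matches the closed-form conversion algebra", {
  # expected observed C fraction = m (1 - over) + (1 - m)(1 - e)
  tx <- data.frame(id = "tx1",
                   sequence = paste(rep("AACGGTTAGG", 30), collapse = ""),
                   is_spikein = FALSE)
  site <- char_positions0(tx$sequence)[2]
  cases <- list(c(m = 0.5, e = 0.99, over = 0),
                c(m = 0.8, e = 0.95, over = 0.05),
                c(m = 0.0, e = 0.97, over = 0))
  for (cs in cases) {
    truth <- assign_truth(tx, sites = data.frame(transcript_id = "tx1",
                                                 pos = site, m_EV = cs[["m"]],
                                                 m_NSUN7 = cs[["m"]]))
    cfg <- sim_config(e = cs[["e"]], overconversion = cs[["over"]],
                      seq_error = 0, mean_depth = 1500, read_length = 75,
                      seed = 9)
    rd <- bisulfite_reads(tx, truth, cfg, "EV", 1)
    over_reads <- rd[rd$start <= site & rd$start + 75 > site, ]
    b <- substr(over_reads$sequence, site - over_reads$start + 1,
                site - over_reads$start + 1)
    n <- sum(b %in% c("C", "T"))
    expected <- cs[["m"]] * (1 - cs[["over"]]) + (1 - cs[["m"]]) * (1 - cs[["e"]])
    tol <- 4 * sqrt(max(expected * (1 - expected), 1e-4) / n)
    expect_lt(abs(mean(b == "C") - expected), max(tol, 0.05))
  }
})

test_that("read count follows the documented rounding rule and short transcripts warn", {
  tx <- data.frame(id = c("long", "short"),
                   sequence = c(strrep("ACGT", 50), "ACGT"),
                   is_spikein = c(FALSE, FALSE))
  cfg <- sim_config(mean_depth = 10, read_length = 50, seq_error = 0, seed = 1)
  truth <- assign_truth(tx[0, ], conditions = c("EV", "NSUN7"))
  expect_warning(rd <- bisulfite_reads(tx, truth, cfg, "EV", 1), "skipped")
  expect_equal(nrow(rd), round(10 * 200 / 50))
  expect_false("short" %in% rd$transcript_id)
  expect_error(bisulfite_reads(tx, truth, cfg, "EV", 5), "replicate")
})

test_that("FASTQ written read sets re-parse to identical records", {
  tx <- fixture_transcripts()
  cfg <- sim_config(mean_depth = 5, seed = 2)
  rd <- bisulfite_reads(tx, assign_truth(tx), cfg, "EV", 1)
  path <- tempfile(fileext = ".fastq")
  on.exit(unlink(path))
  write_reads_fastq(rd, path)
  back <- read_reads_fastq(path)
  expect_identical(back$read_id, rd$read_id)
  expect_identical(back$sequence, rd$sequence)
})

test_that("clone simulator: conversion limits, rounding contract, flag determinism", {
  ref <- paste(rep("TACGGA", 20), collapse = "")
  cs0 <- clone_sequences(ref, m_true = 0, n_clones = 6, incomplete_fraction = 0,
                         e_good = 1, seed = 4)
  expect_true(all(!grepl("C", cs0$clones)))        # every C converted
  expect_true(all(cs0$truth_states == "U"))

  cs1 <- clone_sequences(ref, m_true = 1, n_clones = 6, incomplete_fraction = 0,
                         e_good = 1, seed = 4)
  expect_true(all(cs1$truth_states == "M"))
  expect_identical(cs1$clones, setNames(rep(ref, 6), names(cs1$clones)))

  cs2 <- clone_sequences(ref, m_true = 0.5, n_clones = 12,
                         incomplete_fraction = 0.25, e_good = 0.99,
                         e_bad = 0.7, seed = 8)
  expect_equal(sum(cs2$incomplete_flags), 3)       # round(0.25 * 12)

  expect_error(clone_sequences(ref, n_clones = 4, incomplete_fraction = 0.5,
                               e_good = 0.9, e_bad = 0.95),
               "e_bad")
  cs3 <- clone_sequences(ref, m_true = 0.5, n_clones = 12,
                         incomplete_fraction = 0.25, e_good = 0.99,
                         e_bad = 0.7, seed = 8)
  expect_identical(cs2$clones, cs3$clones)
})

test_that("association-table simulator separates groups as specified and is seeded", {
  at <- simulate_assoc_tables(50, seed = 3)
  at2 <- simulate_assoc_tables(50, seed = 3)
  expect_identical(at, at2)
  expect_true(all(at$samples$mean_beta >= 0 & at$samples$mean_beta <= 1))

  # strong effect: beta and expression anti-correlate in nearly every seed
  hits <- 0L
  for (s in 1:200) {
    tt <- simulate_assoc_tables(50, seed = s)
    if (spearman_assoc(tt$samples$mean_beta, tt$samples$expression)$rho < 0)
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)

  # zero effect: group means differ only by noise
  null_eff <- list(beta_meth = 0.4, beta_unmeth = 0.4, beta_sd = 0.05,
                   expr_meth = 0, expr_unmeth = 0, expr_sd = 0.5)
  nt <- simulate_assoc_tables(100, effect = null_eff, seed = 5)
  g <- split(nt$samples$expression, nt$samples$group)
  expect_gt(ttest_groups(g[[1]], g[[2]])$p, 0.001)
})
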