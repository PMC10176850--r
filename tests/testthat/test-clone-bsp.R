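test_that("scored positions follow the mode definition", {
  expect_equal(find_scored_positions("ACGTCGC", "DNA-CpG"), c(1, 4))
  expect_equal(find_scored_positions("ACGTCGC", "RNA-anyC"), c(1, 4, 6))
  expect_equal(find_scored_positions("AGTTAGT", "RNA-anyC"), integer(0))
  # a terminal C is never CpG context
  expect_equal(find_scored_positions("GGC", "DNA-CpG"), integer(0))
})

test_that("bisulfite-aware alignment treats conversion as identity", {
  ref <- "TTGACCGGATTCCAATTGGAACCTTGGAATT"
  conv <- chartr("C", "T", ref)
  a1 <- align_clone(conv, ref)
  expect_equal(a1$status, "aligned")
  expect_equal(a1$identity, 1)
  expect_equal(a1$ref_base, strsplit(conv, "")[[1]])

  a2 <- align_clone(ref, ref)
  expect_equal(a2$identity, 1)
  expect_equal(a2$ref_base, strsplit(ref, "")[[1]])

  # but a clone C at a reference T is a mismatch (asymmetric scoring)
  refT <- "TTTTTTTTTTTTTTTTTTTT"
  aC <- align_clone("TTTTTTTTTTCTTTTTTTTT", refT)
  expect_lt(aC$identity, 1)
})

test_that("a one-base deletion shifts nothing: downstream positions are recovered", {
  set.seed(12)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  conv <- chartr("C", "T", ref)
  # drop base 30 of the converted clone
  clone <- paste0(substr(conv, 1, 29), substr(conv, 31, 60))
  a <- align_clone(clone, ref)
  expect_equal(a$status, "aligned")
  # every reference position except the deleted one aligns to its base
  expect_equal(a$ref_base[-30], strsplit(conv, "")[[1]][-30])
  expect_true(is.na(a$ref_base[30]))
})

test_that("unalignable clones are discarded by length and identity floors", {
  ref <- strrep("ACGT", 20)
  short <- substr(ref, 1, 40)   # 50% of the reference length
  expect_equal(align_clone(short, ref)$status, "discarded-unalignable")
  junk <- strrep("G", 80)
  expect_equal(align_clone(junk, ref)$status, "discarded-unalignable")
})

test_that("isolated methylated calls are flagged X; recurrent calls are kept", {
  states <- matrix("U", 12, 5,
                   dimnames = list(sprintf("clone%02d", 1:12), 1:5))
  states[1, 2] <- "M"                     # one clone only -> X
  states[1:9, 4] <- "M"                   # 9/12 clones -> kept
  fl <- flag_inconsistent(states)
  expect_equal(fl$states[1, 2], "X")
  expect_true(all(fl$states[1:9, 4] == "M"))
  expect_true(all(fl$verdicts == "kept"))  # one X call is below min_x_calls
})

test_that("a cluster methylated in most clones survives intact", {
  # the three-consecutive-site pattern: 3 positions methylated in 9/12 clones
  states <- matrix("U", 12, 8,
                   dimnames = list(sprintf("clone%02d", 1:12), 1:8))
  states[1:9, 3:5] <- "M"
  fl <- flag_inconsistent(states)
  expect_true(all(fl$states[1:9, 3:5] == "M"))
  expect_true(all(fl$verdicts == "kept"))
})

test_that("clones dominated by inconsistent calls are discarded as incomplete", {
  states <- matrix("U", 12, 20,
                   dimnames = list(sprintf("clone%02d", 1:12), 1:20))
  states[1, c(2, 7, 11, 15, 19)] <- "M"   # five isolated calls, one clone
  fl <- flag_inconsistent(states)
  expect_equal(unname(fl$verdicts["clone01"]), "discarded-incomplete")
  expect_true(all(fl$verdicts[-1] == "kept"))
})

test_that("kept-clone states equal the simulator's pre-conversion draws at e_good = 1", {
  set.seed(2)
  ref <- paste(sample(c("A", "C", "G", "T"), 180, TRUE,
                      prob = c(0.3, 0.25, 0.2, 0.25)), collapse = "")
  sc <- find_scored_positions(ref, "RNA-anyC")
  m <- setNames(rep(0, length(sc)), sc)
  m[as.character(sc[5:7])] <- 0.8
  cs <- clone_sequences(ref, m_true = m, n_clones = 12,
                        incomplete_fraction = 0, e_good = 1, seed = 9)
  cm <- analyze_clones(cs)
  expect_true(all(cm$verdicts == "kept"))
  expect_identical(dimnames(cm$states), dimnames(cs$truth_states))
  expect_identical(cm$states, cs$truth_states)
})

test_that("clone analysis summary reports percents over kept clones", {
  ref <- "TTACGTTACGTTACGTT"            # three Cs
  mk <- function(pattern) {
    chars <- strsplit(chartr("C", "T", ref), "")[[1]]
    cpos <- find_scored_positions(ref, "RNA-anyC")
    chars[cpos[pattern] + 1] <- "C"
    paste(chars, collapse = "")
  }
  clones <- c(replicate(6, mk(1:3)), replicate(4, mk(integer(0))))
  names(clones) <- sprintf("c%02d", 1:10)
  cm <- analyze_clones(clones, ref, "RNA-anyC")
  s <- summarize_clones(cm)
  expect_equal(s$table$percent, rep(60, 3))        # 6 M / 4 U
  expect_equal(s$n_kept, 10)
  expect_length(s$lollipop, 10)

  all_u <- analyze_clones(setNames(replicate(10, mk(integer(0))),
                                   sprintf("u%02d", 1:10)), ref, "RNA-anyC")
  expect_equal(unname(summarize_clones(all_u)$table$percent), rep(0, 3))
  all_m <- analyze_clones(setNames(replicate(10, mk(1:3)),
                                   sprintf("m%02d", 1:10)), ref, "RNA-anyC")
  expect_equal(unname(summarize_clones(all_m)$table$percent), rep(100, 3))
})

test_that("percents are invariant to clone input order", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  sc <- find_scored_positions(ref, "RNA-anyC")
  cs <- clone_sequences(ref, m_true = 0.5, n_clones = 12,
                        incomplete_fraction = 0, e_good = 1, seed = 14)
  cm1 <- analyze_clones(cs)
  shuffled <- cs$clones[sample(length(cs$clones))]
  cm2 <- analyze_clones(shuffled, ref, "RNA-anyC")
  expect_equal(sort(cm1$percent), sort(cm2$percent))
  expect_equal(unname(cm1$percent), unname(cm2$percent))
})

test_that("DNA-mode non-CpG conversion QC discards unconverted clones", {
  # reference with CpG and non-CpG cytosines
  ref <- "TTCGATTCATTCGATTCATTCGATTCATTCGATTCATT"
  cpg <- find_scored_positions(ref, "DNA-CpG")
  allc <- which(strsplit(ref, "")[[1]] == "C") - 1
  noncpg <- setdiff(allc, cpg)
  expect_gt(length(noncpg), 0)

  full <- chartr("C", "T", ref)            # every C converted
  bases <- function(s) strsplit(s, "")[[1]]
  rb <- list(good = bases(full), bad = bases(ref))  # 'bad' kept all Cs
  qc <- dna_conversion_qc(rb, ref)
  expect_equal(qc$rate[qc$clone == "good"], 1.0)
  expect_true(qc$pass[qc$clone == "good"])
  expect_equal(qc$rate[qc$clone == "bad"], 0.0)
  expect_equal(qc$status[qc$clone == "bad"], "discarded-incomplete")

  no_noncpg <- "TTCGTTCGTT"
  expect_equal(dna_conversion_qc(list(a = bases(chartr("C", "T", no_noncpg))),
                                 no_noncpg)$status,
               "unavailable")
})

test_that("too few clones yields a low-confidence warning, not an abort", {
  ref <- strrep("TACG", 30)
  cs <- clone_sequences(ref, m_true = 0, n_clones = 4, incomplete_fraction = 0,
                        e_good = 1, seed = 6)
  expect_warning(cm <- analyze_clones(cs), "low-confidence")
  expect_true(cm$low_confidence)
  expect_equal(cm$n_kept, 4)
})
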