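# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the Fisher oracle enumerates tables with choose(), the
# pileup oracle recounts coverage read by read, and the site-calling oracle
# is a literal transcription of the filter rules.

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins, probabilities from binomial coefficients.
fisher_oracle <- function(c_a, t_a, c_b, t_b) {
  N <- c_a + t_a + c_b + t_b
  m <- c_a + c_b          # column-1 margin
  k <- c_a + t_a          # row-A margin
  xs <- max(0L, k - (N - m)):min(k, m)
  probs <- choose(m, xs) * choose(N - m, k - xs) / choose(N, k)
  p_obs <- probs[xs == c_a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Literal transcription of the candidate-site rules: both replicates pass
# coverage >= 30, C depth >= 5, (c+t)/coverage >= 0.8, and the average
# non-conversion level across replicates >= 0.1; or exactly one replicate
# passes those filters and that replicate also passes the stricter C depth
# >= 7 with its own non-conversion level >= 0.1.
brute_force_candidate <- function(cov1, c1, t1, cov2, c2, t2,
                                  min_cov = 30, min_c = 5, min_c_strict = 7,
                                  min_ct = 0.8, min_m = 0.1) {
  rep_pass <- function(cov, cc, tt, c_need) {
    !is.na(cov) && cov >= min_cov && cc >= c_need &&
      (cc + tt) / cov >= min_ct
  }
  m_of <- function(cc, tt) if (cc + tt > 0) cc / (cc + tt) else NA_real_
  p1 <- rep_pass(cov1, c1, t1, min_c)
  p2 <- rep_pass(cov2, c2, t2, min_c)
  m1 <- m_of(c1, t1)
  m2 <- m_of(c2, t2)
  if (p1 && p2) {
    avg <- mean(c(m1, m2), na.rm = TRUE)
    return(!is.na(avg) && avg >= min_m)
  }
  if (xor(p1, p2)) {
    if (p1) return(rep_pass(cov1, c1, t1, min_c_strict) && !is.na(m1) && m1 >= min_m)
    return(rep_pass(cov2, c2, t2, min_c_strict) && !is.na(m2) && m2 >= min_m)
  }
  FALSE
}

# Brute-force recount of pileup coverage: for every read, count the
# reference-C positions it spans; the total must equal the summed pileup
# coverage (conservation).
pileup_coverage_oracle <- function(alignments, reads, transcripts) {
  aln <- alignments[alignments$status == "unique", ]
  total <- 0L
  for (i in seq_len(nrow(aln))) {
    seqc <- transcripts$sequence[transcripts$id == aln$transcript_id[i]]
    L <- nchar(reads$sequence[reads$read_id == aln$read_id[i]])
    span <- substr(seqc, aln$start[i] + 1L, aln$start[i] + L)
    total <- total + lengths(regmatches(span, gregexpr("C", span, fixed = TRUE)))
  }
  total
}

# Small random pileup row generator used by filter tests.
random_pileup_rows <- function(n, seed) {
  set.seed(seed)
  cov <- sample(0:80, n, replace = TRUE)
  cc <- integer(n); tt <- integer(n); oo <- integer(n)
  for (i in seq_len(n)) {
    parts <- stats::rmultinom(1, cov[i], prob = c(0.25, 0.65, 0.10))
    cc[i] <- parts[1]; tt[i] <- parts[2]; oo[i] <- parts[3]
  }
  data.frame(coverage = cov, c = cc, t = tt, other = oo)
}

# Tiny deterministic fixture shared across mapper/pileup tests: two
# transcripts whose collapsed k-mer sets are disjoint (verified where the
# test needs it).
fixture_transcripts <- function(len = 300, seed = 42) {
  make_transcriptome(2, len, gc_fraction = 0.5, n_spikeins = 1, seed = seed)
}
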