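test_that("fisher_site matches exact enumeration on fixed and random tables", {
  # identical tables: p = 1
  expect_equal(fisher_site(10, 90, 10, 90), 1.0)
  # (0,5,5,0): 6 tables with margins (5,5,5,5); the two extremes have
  # probability 1/252 each -> p = 2/252
  expect_equal(fisher_site(0, 5, 5, 0), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_site(5, 95, 30, 70),
               fisher_oracle(5, 95, 30, 70), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:50) {
    x <- as.integer(sample(0:30, 4, replace = TRUE))
    if (x[1] + x[2] == 0 || x[3] + x[4] == 0) next
    expect_equal(fisher_site(x[1], x[2], x[3], x[4]),
                 fisher_oracle(x[1], x[2], x[3], x[4]), tolerance = 1e-12)
  }
  # untestable and invalid input
  expect_true(is.na(fisher_site(0, 0, 5, 5)))
  expect_error(fisher_site(-1, 5, 5, 5), "non-negative")
})

test_that("fisher_site agrees with the standard exact-test implementation", {
  set.seed(23)
  for (i in 1:50) {
    x <- as.integer(sample(0:40, 4, replace = TRUE))
    if (x[1] + x[2] == 0 || x[3] + x[4] == 0) next
    ref <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
    expect_equal(fisher_site(x[1], x[2], x[3], x[4]), ref, tolerance = 1e-9)
  }
})

test_that("BH adjustment: closed-form example, identity at n=1, dominance", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03)), c(0.003, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  p <- runif(200)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\(0, 1\\]")
})

test_that("the significance rule requires both adjusted p and delta", {
  # strong p but delta 0.05: never significant
  pu_a <- data.frame(transcript_id = "t1", pos = 0, pos_1based = 1,
                     replicate = 1, c = 500, t = 9500, other = 0,
                     coverage = 10000, m = 0.05)
  pu_b <- pu_a
  pu_b$c <- 1000; pu_b$t <- 9000; pu_b$m <- 0.1
  d <- call_differential(pu_a, pu_b)
  expect_lt(d$p_adj, 1e-6)
  expect_equal(d$delta, 0.05)
  expect_false(d$significant)
})

test_that("replicates are pooled within condition before testing", {
  pu_a <- data.frame(transcript_id = "t1", pos = c(0, 0), pos_1based = 1,
                     replicate = c(1, 2), c = c(3, 4), t = c(47, 46),
                     other = 0, coverage = 50, m = c(0.06, 0.08))
  pu_b <- data.frame(transcript_id = "t1", pos = c(0, 0), pos_1based = 1,
                     replicate = c(1, 2), c = c(30, 32), t = c(20, 18),
                     other = 0, coverage = 50, m = c(0.6, 0.64))
  d <- call_differential(pu_a, pu_b)
  expect_equal(d$c_a, 7)
  expect_equal(d$t_a, 93)
  expect_equal(d$c_b, 62)
  expect_equal(d$t_b, 38)
  expect_equal(d$p_raw, fisher_oracle(7, 93, 62, 38), tolerance = 1e-12)
  expect_true(d$significant)
})

test_that("swapping condition labels negates delta and preserves p-values", {
  set.seed(71)
  mk <- function(cc, tt) data.frame(transcript_id = "t1", pos = 0:(length(cc) - 1),
                                    pos_1based = seq_along(cc), replicate = 1,
                                    c = cc, t = tt, other = 0,
                                    coverage = cc + tt,
                                    m = nonconversion_level(cc, tt))
  a <- mk(sample(5:50, 20), sample(20:80, 20))
  b <- mk(sample(5:50, 20), sample(20:80, 20))
  d1 <- call_differential(a, b)
  d2 <- call_differential(b, a)
  expect_equal(d1$delta, -d2$delta)
  expect_equal(d1$p_raw, d2$p_raw)
  expect_equal(d1$p_adj, d2$p_adj)
})

test_that("gain_only restricts significance to methylation gain", {
  mk1 <- function(cc, tt) data.frame(transcript_id = "t1", pos = 0,
                                     pos_1based = 1, replicate = 1, c = cc,
                                     t = tt, other = 0, coverage = cc + tt,
                                     m = cc / (cc + tt))
  d_loss <- call_differential(mk1(60, 40), mk1(5, 95), gain_only = TRUE)
  expect_false(d_loss$significant)
  d_loss2 <- call_differential(mk1(60, 40), mk1(5, 95), gain_only = FALSE)
  expect_true(d_loss2$significant)
})

test_that("candidate-union restriction and empty test sets behave as documented", {
  mk <- function(pos, cc, tt) data.frame(transcript_id = "t1", pos = pos,
                                         pos_1based = pos + 1, replicate = 1,
                                         c = cc, t = tt, other = 0,
                                         coverage = cc + tt,
                                         m = nonconversion_level(cc, tt))
  a <- mk(c(0, 5), c(10, 20), c(90, 80))
  b <- mk(c(0, 5), c(50, 20), c(50, 80))
  d <- call_differential(a, b, candidates = data.frame(transcript_id = "t1",
                                                       pos = 0))
  expect_equal(nrow(d), 1)
  expect_equal(d$pos, 0)
  expect_message(
    d0 <- call_differential(a, b, candidates = data.frame(transcript_id = "t9",
                                                          pos = 1)),
    "empty")
  expect_equal(nrow(d0), 0)
})

test_that("ranking orders by adjusted p, then |delta|, then locus", {
  d <- data.frame(transcript_id = c("b", "a", "a", "a"),
                  pos = c(3, 9, 1, 1), pos_1based = c(4, 10, 2, 2),
                  c_a = 0, t_a = 1, c_b = 1, t_b = 0, m_a = 0, m_b = 1,
                  delta = c(0.8, 0.9, 0.3, 0.9),
                  p_raw = c(1e-5, 1e-3, 1e-3, 1e-3),
                  p_adj = c(1e-5, 1e-3, 1e-3, 1e-3),
                  significant = TRUE)
  r <- rank_top(d)
  expect_equal(r$p_adj[1], 1e-5)                    # smallest p first
  expect_equal(r$delta[2], 0.9)                     # then larger |delta|
  expect_equal(r$transcript_id[2], "a")             # lexicographic tie-break
  expect_equal(r$pos[2], 1)
  expect_equal(r$rank, 1:4)
  expect_error(rank_top(d[0, ]), "empty")
})
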