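#' Two-sided Fisher's exact test for one site (2x2 C/T counts)
#'
#' Exact two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table. Tie inclusion
#' uses the classical `1 + 1e-7` relative tolerance (the convention shared
#' by the standard implementations), documented because two-sided Fisher
#' conventions differ.
#'
#' @param c_a,t_a C and T counts in condition A (pooled over replicates).
#' @param c_b,t_b C and T counts in condition B.
#' @return p-value in `(0, 1]`, or NA when a condition has c + t = 0
#'   (untestable).
#' @export
fisher_site <- function(c_a, t_a, c_b, t_b) {
  counts <- c(c_a, t_a, c_b, t_b)
  if (any(counts < 0) || any(counts != trunc(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (c_a + t_a == 0 || c_b + t_b == 0) return(NA_real_)
  m <- c_a + c_b          # total C (first column margin)
  n <- t_a + t_b          # total T
  k <- c_a + t_a          # row-A margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(c_a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: sort ascending, q_i = p_i * n / i,
#' enforce monotonicity from the largest rank down, cap at 1, restore the
#' input order. Thin, validated surface over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values in the input order, elementwise >= `p`.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Differential methylation between two conditions
#'
#' Per site, replicates are pooled within condition and a two-sided Fisher
#' exact test compares the C/T counts between conditions. P-values are
#' corrected over the test set; a site is significant iff the adjusted
#' p-value is below `alpha` and the methylation difference exceeds
#' `min_delta` (in absolute value by default; `gain_only` restricts to
#' methylation gain in condition B).
#'
#' The test set comprises sites that are candidates in at least one
#' condition (when a candidate union is supplied) and have pooled c + t >= 1
#' in both conditions.
#'
#' @param pileup_a,pileup_b pileup tables (all replicates) for conditions A
#'   and B.
#' @param candidates optional candidate union: data.frame with
#'   `transcript_id` and `pos` (e.g. rbind of [call_sites()] candidate rows
#'   from each condition). NULL tests every site covered in both conditions.
#' @param alpha adjusted-p significance level (default 0.01).
#' @param min_delta minimum methylation difference (default 0.1).
#' @param method correction method for [bh_adjust()].
#' @param gain_only require `delta > min_delta` instead of
#'   `|delta| > min_delta`.
#' @return data.frame: `transcript_id`, `pos`, `pos_1based`, `c_a`, `t_a`,
#'   `c_b`, `t_b`, `m_a`, `m_b`, `delta` (= m_b - m_a), `p_raw`, `p_adj`,
#'   `significant`; attribute `"correction"` records the method.
#' @export
call_differential <- function(pileup_a, pileup_b, candidates = NULL,
                              alpha = 0.01, min_delta = 0.1,
                              method = "BH", gain_only = FALSE) {
  pool <- function(p) {
    dt <- data.table::as.data.table(p)
    as.data.frame(dt[, list(c = sum(c), t = sum(t)),
                     by = c("transcript_id", "pos")])
  }
  a <- pool(pileup_a)
  b <- pool(pileup_b)
  key_a <- paste(a$transcript_id, a$pos)
  key_b <- paste(b$transcript_id, b$pos)
  keys <- intersect(key_a, key_b)
  if (!is.null(candidates)) {
    ck <- unique(paste(candidates$transcript_id, candidates$pos))
    keys <- intersect(keys, ck)
  }
  ia <- match(keys, key_a)
  ib <- match(keys, key_b)
  res <- data.frame(transcript_id = a$transcript_id[ia], pos = a$pos[ia],
                    c_a = a$c[ia], t_a = a$t[ia],
                    c_b = b$c[ib], t_b = b$t[ib], stringsAsFactors = FALSE)
  res <- res[res$c_a + res$t_a >= 1L & res$c_b + res$t_b >= 1L, , drop = FALSE]
  if (nrow(res) == 0L) {
    message("differential test set is empty")
    res <- data.frame(transcript_id = character(0), pos = integer(0),
                      pos_1based = integer(0), c_a = integer(0),
                      t_a = integer(0), c_b = integer(0), t_b = integer(0),
                      m_a = numeric(0), m_b = numeric(0), delta = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    attr(res, "correction") <- method
    return(res)
  }
  res <- res[order(res$transcript_id, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res$pos_1based <- res$pos + 1L
  res$m_a <- nonconversion_level(res$c_a, res$t_a)
  res$m_b <- nonconversion_level(res$c_b, res$t_b)
  res$delta <- res$m_b - res$m_a
  res$p_raw <- mapply(fisher_site, res$c_a, res$t_a, res$c_b, res$t_b)
  res$p_adj <- bh_adjust(res$p_raw, method = method)
  res$significant <- res$p_adj < alpha &
    (if (gain_only) res$delta > min_delta else abs(res$delta) > min_delta)
  res <- res[, c("transcript_id", "pos", "pos_1based", "c_a", "t_a",
                 "c_b", "t_b", "m_a", "m_b", "delta", "p_raw", "p_adj",
                 "significant")]
  attr(res, "correction") <- method
  res
}

#' Rank a differential table
#'
#' Orders by adjusted p ascending, then |delta| descending, then
#' (transcript, position) lexicographic so full ties are reproducible, and
#' appends a `rank` column.
#'
#' @param diff table from [call_differential()] (non-empty).
#' @return the table sorted, with a `rank` column.
#' @export
rank_top <- function(diff) {
  if (nrow(diff) == 0L) stop("cannot rank an empty table", call. = FALSE)
  o <- order(diff$p_adj, -abs(diff$delta), diff$transcript_id, diff$pos)
  out <- diff[o, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out
}
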