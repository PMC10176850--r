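#' Mean promoter beta-value for one sample
#'
#' Unweighted arithmetic mean of the per-CpG beta-values of a promoter
#' region; missing input yields NA.
#'
#' @param beta numeric vector of beta-values in `[0,1]`.
#' @return mean beta, or NA for empty input.
#' @export
summarize_promoter_beta <- function(beta) {
  if (length(beta) == 0L) return(NA_real_)
  stopifnot(is_probability(beta))
  mean(beta)
}

#' Dichotomize promoter methylation status
#'
#' Methylated iff mean beta >= `threshold` (boundary inclusive). The 0.30
#' default is a recorded choice exposed as an argument; classification is
#' monotone in beta.
#'
#' @param mean_beta mean beta-value(s) in `[0,1]`.
#' @param threshold dichotomization cut, default 0.30.
#' @return character vector, "methylated" or "unmethylated".
#' @export
classify_promoter <- function(mean_beta, threshold = 0.30) {
  stopifnot(is_probability(mean_beta), is_probability(threshold))
  ifelse(mean_beta >= threshold, "methylated", "unmethylated")
}

#' Spearman rank correlation
#'
#' Rho with average ranks for ties; p-value from the t-approximation
#' (via [stats::cor.test()] with `exact = FALSE`). A constant vector has no
#' rank correlation and returns NA.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list: `rho`, `p`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Shared implementation with the per-site differential test
#' ([fisher_site()]): point-probability two-sided p on the hypergeometric
#' distribution. Rows are the clinical categories, columns the methylation
#' status. A zero margin makes the table untestable (NA).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return p-value, or NA.
#' @export
fisher_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(NA_real_)
  fisher_site(table[1L, 1L], table[1L, 2L], table[2L, 1L], table[2L, 2L])
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Pearson statistic with df = (r-1)(c-1) and upper-tail p, no continuity
#' correction. `exact = "always"` (or `"auto"` when any expected count is
#' below 5, the standard small-count rule) instead computes the exact
#' permutation p-value of the Pearson statistic by full enumeration of all
#' tables with the observed margins — the convention of standard clinical
#' statistics software, which the asymptotic p approximates. Exact
#' enumeration is implemented for two-column tables (the
#' methylated/unmethylated design).
#'
#' @param table r x c matrix of non-negative counts, r >= 2.
#' @param exact `"auto"`, `"never"` or `"always"`.
#' @return list: `statistic`, `df`, `p`, `method` ("asymptotic" or
#'   "exact"); NA p for degenerate margins.
#' @export
chisq_rxc <- function(table, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  stopifnot(is.matrix(table), nrow(table) >= 2L, ncol(table) >= 2L,
            all(table >= 0))
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                method = "untestable"))
  N <- sum(table)
  E <- outer(rs, cs) / N
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  use_exact <- exact == "always" || (exact == "auto" && any(E < 5))
  if (use_exact && ncol(table) == 2L) {
    p <- .chisq_exact_2col(table, stat)
    method <- "exact"
  } else {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    method <- "asymptotic"
  }
  list(statistic = stat, df = df, p = p, method = method)
}

# Exact permutation p of the Pearson statistic for an r x 2 table: sum of
# hypergeometric probabilities of all tables with the observed margins whose
# statistic is >= the observed (within 1e-9, guarding float ties). The last
# two rows are enumerated vectorized; earlier rows by recursion.
.chisq_exact_2col <- function(table, stat_obs) {
  rs <- rowSums(table)
  cs <- colSums(table)
  N <- sum(table)
  r <- length(rs)
  E1 <- rs * cs[1L] / N
  E2 <- rs * cs[2L] / N
  denom <- lchoose(N, cs[1L])
  # chi2 contribution of row i with first-column count x
  contrib <- function(i, x) (x - E1[i])^2 / E1[i] + ((rs[i] - x) - E2[i])^2 / E2[i]
  p <- 0
  rec <- function(i, rem, lp, chi) {
    if (i == r - 1L) {
      lo <- max(0L, rem - rs[r])
      hi <- min(rs[i], rem)
      if (lo > hi) return()
      x <- lo:hi
      xr <- rem - x
      chi2 <- chi + contrib(i, x) + contrib(r, xr)
      lp2 <- lp + lchoose(rs[i], x) + lchoose(rs[r], xr)
      keep <- chi2 >= stat_obs - 1e-9
      p <<- p + sum(exp(lp2[keep] - denom))
      return()
    }
    lo <- max(0L, rem - sum(rs[(i + 1L):r]))
    hi <- min(rs[i], rem)
    if (lo > hi) return()
    for (x in lo:hi)
      rec(i + 1L, rem - x, lp + lchoose(rs[i], x), chi + contrib(i, x))
  }
  rec(1L, cs[1L], 0, 0)
  min(1, p)
}

#' Two-group Student's t-test
#'
#' Two-sided pooled-variance Student's t by default; Welch by flag. Two
#' groups with zero variance and equal means return t = 0, p = 1 (the
#' documented degenerate convention).
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) test.
#' @return list: `t`, `p`, `df`.
#' @export
ttest_groups <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, p = 1, df = length(values_a) + length(values_b) - 2L))
    return(list(t = Inf * sign(mean(values_a) - mean(values_b)), p = 0,
                df = length(values_a) + length(values_b) - 2L))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' mRNA half-life from an actinomycin D chase series
#'
#' Transcription is blocked at t = 0 and relative transcript abundance
#' (normalized to a housekeeping gene and to t = 0) follows first-order
#' decay; the half-life is estimated by least squares on the log scale:
#' t1/2 = ln 2 / (-slope) of `ln(abundance) ~ time`. A flat or increasing
#' series has no measurable decay and returns an infinite half-life with a
#' flag.
#'
#' @param time timepoints in hours, >= 3 values including 0.
#' @param abundance relative abundances, strictly positive.
#' @return list: `t_half` (hours; may be Inf), `slope` (per hour),
#'   `finite` (logical flag).
#' @export
halflife <- function(time, abundance) {
  stopifnot(length(time) == length(abundance))
  if (length(time) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  if (!any(time == 0)) stop("timepoints must include t = 0", call. = FALSE)
  if (any(abundance <= 0)) stop("abundances must be positive", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(log(abundance) ~ time))[2L])
  if (slope >= 0) return(list(t_half = Inf, slope = slope, finite = FALSE))
  list(t_half = log(2) / (-slope), slope = slope, finite = TRUE)
}

#' Clinicopathological counts of the TCGA liver cohort
#'
#' The published contingency tables of clinicopathological variables versus
#' promoter methylation status in the TCGA LIHC cohort (columns:
#' unmethylated, methylated). Dichotomous variables are tested with
#' [fisher_2x2()], categorical ones with [chisq_rxc()].
#'
#' @return named list of count matrices, each with a `test` attribute
#'   ("fisher" or "chisq").
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "tcga_lihc_table1.tsv", package = "bsm5c")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(raw, raw$variable), function(d) {
    m <- as.matrix(d[, c("unmethylated", "methylated")])
    rownames(m) <- d$category
    attr(m, "test") <- d$test[1L]
    m
  })
  out[unique(raw$variable)]
}

#' Association report over clinicopathological tables
#'
#' Runs the appropriate test (Fisher 2x2 for dichotomous, chi-square for
#' categorical variables) on each contingency table and returns a tidy
#' report.
#'
#' @param tables named list of count matrices with `test` attributes, as
#'   from [table1_counts()].
#' @return data.frame: `variable`, `test`, `statistic`, `p`, `n`.
#' @export
association_report <- function(tables = table1_counts()) {
  rows <- lapply(names(tables), function(v) {
    m <- tables[[v]]
    if (identical(attr(m, "test"), "fisher")) {
      data.frame(variable = v, test = "fisher", statistic = NA_real_,
                 p = fisher_2x2(m), n = sum(m), stringsAsFactors = FALSE)
    } else {
      cs <- chisq_rxc(m)
      data.frame(variable = v, test = paste0("chisq-", cs$method),
                 statistic = cs$statistic, p = cs$p, n = sum(m),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
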