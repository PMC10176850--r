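#' Candidate m5C site-calling thresholds
#'
#' The filter family applied per replicate and site: minimum read coverage
#' (`30RC`), minimum number of reads showing C (`5C`, strict `7C`), minimum
#' fraction of bases read as C or T (`80CT`), and minimum average
#' non-conversion level (`10MM`).
#'
#' @param min_coverage minimum coverage per replicate (30RC), default 30.
#' @param min_c minimum C depth (5C), default 5.
#' @param min_c_strict strict C depth for the single-replicate fallback
#'   (7C), default 7; must be >= `min_c`.
#' @param min_ct_fraction minimum (c+t)/coverage (80CT), default 0.80.
#' @param min_avg_m minimum average non-conversion level (10MM), default 0.10.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_coverage = 30L, min_c = 5L, min_c_strict = 7L,
                              min_ct_fraction = 0.80, min_avg_m = 0.10) {
  if (min_c_strict < min_c) stop("min_c_strict must be >= min_c", call. = FALSE)
  stopifnot(is_probability(min_ct_fraction), is_probability(min_avg_m))
  structure(list(min_coverage = min_coverage, min_c = min_c,
                 min_c_strict = min_c_strict, min_ct_fraction = min_ct_fraction,
                 min_avg_m = min_avg_m),
            class = "filter_thresholds")
}

#' Per-replicate filter flags for one or more sites
#'
#' Evaluates the coverage (30RC), C-depth (5C or strict 7C) and C/T-fraction
#' (80CT) filters; the methylation-level criterion (10MM) is a site-level
#' rule evaluated in [call_sites()], not here. Vectorized over rows. A
#' missing replicate (NA coverage) fails all flags.
#'
#' @param coverage,c_count,t_count per-replicate counts.
#' @param thresholds a [filter_thresholds()].
#' @param strict apply the strict C-depth (7C) instead of 5C.
#' @return data.frame of logicals: `pass_30rc`, `pass_c`, `pass_80ct`,
#'   `pass` (conjunction), `missing`.
#' @export
replicate_passes <- function(coverage, c_count, t_count, thresholds,
                             strict = FALSE) {
  miss <- is.na(coverage) | coverage == 0L
  cov <- ifelse(miss, 0L, coverage)
  cc <- ifelse(is.na(c_count), 0L, c_count)
  tt <- ifelse(is.na(t_count), 0L, t_count)
  p_rc <- cov >= thresholds$min_coverage
  p_c <- cc >= (if (strict) thresholds$min_c_strict else thresholds$min_c)
  p_ct <- ifelse(cov > 0L, (cc + tt) / cov >= thresholds$min_ct_fraction, FALSE)
  data.frame(pass_30rc = p_rc & !miss, pass_c = p_c & !miss,
             pass_80ct = p_ct & !miss,
             pass = p_rc & p_c & p_ct & !miss, missing = miss)
}

#' Call candidate m5C sites for one condition
#'
#' A site is a candidate iff (a) both replicates pass the non-strict filters
#' (30RC, 5C, 80CT) and the average non-conversion level across replicates
#' is at least `min_avg_m` (`pass_mode = "both-replicates"`); else (b)
#' exactly one replicate passes the non-strict filters, that same replicate
#' also passes the strict filters (30RC, 7C, 80CT) and its own m is at
#' least `min_avg_m` (`pass_mode = "single-strict"`). In the single-strict
#' branch the 10MM criterion is applied to the passing replicate alone (an
#' average across replicates is unavailable by construction). A replicate
#' entirely missing from the pileup is treated as failing, which routes the
#' site into the fallback branch.
#'
#' @param pileup pileup table for one condition (long format, replicate
#'   column); see [build_pileup()].
#' @param thresholds a [filter_thresholds()].
#' @param replicates the replicate indices of the design; the two-replicate
#'   design is the default, other counts must be requested explicitly via
#'   `allow_any_replicates`.
#' @param allow_any_replicates permit designs with more or fewer than two
#'   replicates ("all pass" replaces "both pass"; fallback requires exactly
#'   one passing replicate passing strict).
#' @param weighted_avg_m use the coverage-weighted (pooled-count) average m
#'   instead of the default unweighted mean of per-replicate m values.
#' @return data.frame, one row per site: `transcript_id`, `pos`,
#'   `pos_1based`, per-replicate `rep<k>_c/_t/_other/_cov/_m`, `avg_m`,
#'   `pass_mode` (NA for non-candidates), `candidate`.
#' @export
call_sites <- function(pileup, thresholds = filter_thresholds(),
                       replicates = NULL, allow_any_replicates = FALSE,
                       weighted_avg_m = FALSE) {
  if (is.null(replicates)) replicates <- sort(unique(pileup$replicate))
  if (length(replicates) == 0L) replicates <- 1:2
  if (length(replicates) != 2L && !allow_any_replicates)
    stop(sprintf(paste0("the design has 2 replicates per condition; got %d. ",
                        "Set allow_any_replicates = TRUE to generalize."),
                 length(replicates)), call. = FALSE)
  nr <- length(replicates)
  dt <- data.table::as.data.table(pileup)
  sites <- unique(dt[, c("transcript_id", "pos"), with = FALSE])
  data.table::setorder(sites, transcript_id, pos)
  wide <- as.data.frame(sites)
  wide$pos_1based <- wide$pos + 1L
  for (j in seq_len(nr)) {
    sub <- dt[replicate == replicates[j]]
    idx <- match(paste(wide$transcript_id, wide$pos),
                 paste(sub$transcript_id, sub$pos))
    wide[[sprintf("rep%d_c", j)]] <- sub$c[idx]
    wide[[sprintf("rep%d_t", j)]] <- sub$t[idx]
    wide[[sprintf("rep%d_other", j)]] <- sub$other[idx]
    wide[[sprintf("rep%d_cov", j)]] <- sub$coverage[idx]
    wide[[sprintf("rep%d_m", j)]] <- sub$m[idx]
  }
  pass_ns <- matrix(FALSE, nrow(wide), nr)
  pass_st <- matrix(FALSE, nrow(wide), nr)
  for (j in seq_len(nr)) {
    cov <- wide[[sprintf("rep%d_cov", j)]]
    cc <- wide[[sprintf("rep%d_c", j)]]
    tt <- wide[[sprintf("rep%d_t", j)]]
    pass_ns[, j] <- replicate_passes(cov, cc, tt, thresholds, strict = FALSE)$pass
    pass_st[, j] <- replicate_passes(cov, cc, tt, thresholds, strict = TRUE)$pass
  }
  mmat <- as.matrix(wide[, sprintf("rep%d_m", seq_len(nr)), drop = FALSE])
  avg_m <- if (weighted_avg_m) {
    cmat <- as.matrix(wide[, sprintf("rep%d_c", seq_len(nr)), drop = FALSE])
    tmat <- as.matrix(wide[, sprintf("rep%d_t", seq_len(nr)), drop = FALSE])
    rowSums(cmat, na.rm = TRUE) /
      pmax(1, rowSums(cmat, na.rm = TRUE) + rowSums(tmat, na.rm = TRUE))
  } else {
    rowMeans(mmat, na.rm = TRUE)
  }
  avg_m[is.nan(avg_m)] <- NA_real_
  n_pass <- rowSums(pass_ns)
  all_pass <- n_pass == nr
  both_mode <- all_pass & !is.na(avg_m) & avg_m >= thresholds$min_avg_m
  single_idx <- which(n_pass == 1L)
  single_mode <- rep(FALSE, nrow(wide))
  for (i in single_idx) {
    j <- which(pass_ns[i, ])
    mj <- mmat[i, j]
    single_mode[i] <- pass_st[i, j] && !is.na(mj) && mj >= thresholds$min_avg_m
  }
  single_mode <- single_mode & !both_mode
  wide$avg_m <- avg_m
  wide$pass_mode <- ifelse(both_mode, "both-replicates",
                           ifelse(single_mode, "single-strict", NA_character_))
  wide$candidate <- both_mode | single_mode
  attr(wide, "thresholds") <- thresholds
  attr(wide, "replicates") <- replicates
  wide
}

#' Summarize a candidate-site table
#'
#' Counts candidates by pass mode and tallies non-candidates by their first
#' failing filter in the fixed order 30RC, 80CT, C-depth, 10MM. The tally
#' uses the most permissive route still open to the site at each step: a
#' site is charged to 30RC when no replicate reaches the coverage floor, to
#' 80CT when no replicate passing 30RC also passes 80CT, to C-depth when the
#' surviving route (both-replicates or single-strict) fails on C depth, and
#' to 10MM otherwise.
#'
#' @param calls table from [call_sites()].
#' @return list: `n_sites`, `n_candidates`, `by_mode` (named counts),
#'   `rejections` (named counts over the four filters).
#' @export
candidate_summary <- function(calls) {
  rej <- c("30RC" = 0L, "80CT" = 0L, "C-depth" = 0L, "10MM" = 0L)
  th <- attr(calls, "thresholds")
  if (is.null(th)) th <- filter_thresholds()
  nr <- length(grep("^rep\\d+_cov$", names(calls)))
  if (nrow(calls) > 0L && nr > 0L) {
    nc <- which(!calls$candidate)
    for (i in nc) {
      cov <- vapply(seq_len(nr), function(j) {
        v <- calls[[sprintf("rep%d_cov", j)]][i]; ifelse(is.na(v), 0, v)
      }, numeric(1L))
      cc <- vapply(seq_len(nr), function(j) {
        v <- calls[[sprintf("rep%d_c", j)]][i]; ifelse(is.na(v), 0, v)
      }, numeric(1L))
      tt <- vapply(seq_len(nr), function(j) {
        v <- calls[[sprintf("rep%d_t", j)]][i]; ifelse(is.na(v), 0, v)
      }, numeric(1L))
      p_rc <- cov >= th$min_coverage
      p_ct <- cov > 0 & (cc + tt) / pmax(cov, 1) >= th$min_ct_fraction
      if (!any(p_rc)) { rej["30RC"] <- rej["30RC"] + 1L; next }
      if (!any(p_rc & p_ct)) { rej["80CT"] <- rej["80CT"] + 1L; next }
      surv <- p_rc & p_ct
      need <- if (sum(surv) == nr && nr > 1L) th$min_c else th$min_c_strict
      if (!any(surv & cc >= need)) { rej["C-depth"] <- rej["C-depth"] + 1L; next }
      rej["10MM"] <- rej["10MM"] + 1L
    }
  }
  by_mode <- c("both-replicates" = sum(calls$pass_mode %in% "both-replicates"),
               "single-strict" = sum(calls$pass_mode %in% "single-strict"))
  list(n_sites = nrow(calls), n_candidates = sum(calls$candidate),
       by_mode = by_mode, rejections = rej)
}
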