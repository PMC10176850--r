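#' Scored cytosine positions of an amplicon reference
#'
#' DNA mode scores the Cs of CpG dinucleotides on the given (top) strand —
#' the positions interrogated by bisulfite sequencing PCR of a promoter CpG
#' island. RNA mode scores every C, since any cytosine of the transcript
#' may carry m5C.
#'
#' @param reference unconverted reference sequence.
#' @param mode `"DNA-CpG"` or `"RNA-anyC"`.
#' @return integer vector of 0-based positions.
#' @export
find_scored_positions <- function(reference, mode = c("RNA-anyC", "DNA-CpG")) {
  mode <- match.arg(mode)
  chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  if (mode == "RNA-anyC") {
    which(chars == "C") - 1L
  } else {
    n <- length(chars)
    which(chars == "C" & c(chars[-1L], "") == "G") - 1L
  }
}

#' Bisulfite-aware global alignment of a clone to its reference
#'
#' Needleman-Wunsch with linear gap penalty and bisulfite-aware scoring: at
#' a reference C, both C and T in the clone score as a match (conversion is
#' never penalized); elsewhere standard match/mismatch. Traceback is
#' deterministic, preferring diagonal, then up (gap in the clone), then
#' left (gap in the reference). A clone whose length deviates more than
#' `max_length_dev` from the reference, or whose bisulfite-aware identity
#' over alignment columns falls below `min_identity`, is
#' `discarded-unalignable`.
#'
#' @param clone clone sequence (Sanger read of one molecule).
#' @param reference unconverted reference.
#' @param match,mismatch,gap alignment scores (gap is per base, linear).
#' @param min_identity identity floor in `[0,1]`, default 0.7.
#' @param max_length_dev allowed relative length deviation, default 0.2.
#' @return list: `status` ("aligned" or "discarded-unalignable"), `score`,
#'   `identity`, `ref_base` (character vector, length = nchar(reference):
#'   the clone base aligned to each reference position, NA at gaps).
#' @export
align_clone <- function(clone, reference, match = 1, mismatch = -1, gap = -2,
                        min_identity = 0.7, max_length_dev = 0.2) {
  n <- nchar(reference)
  m <- nchar(clone)
  if (abs(m - n) > max_length_dev * n)
    return(list(status = "discarded-unalignable", score = NA_real_,
                identity = NA_real_, ref_base = rep(NA_character_, n)))
  rc <- strsplit(reference, "", fixed = TRUE)[[1L]]
  cc <- strsplit(clone, "", fixed = TRUE)[[1L]]
  # substitution score of ref char r vs clone char q
  sub_score <- function(r, q) {
    ok <- r == q | (r == "C" & q == "T")
    ifelse(ok, match, mismatch)
  }
  H <- matrix(0, n + 1L, m + 1L)
  H[1L, ] <- gap * (0:m)
  H[, 1L] <- gap * (0:n)
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    s <- sub_score(rc[i], cc)
    V <- pmax(H[i, jj] + s, H[i, jj + 1L] + gap)   # diag, up
    vals <- c(H[i + 1L, 1L], V) - gap * (0:m)
    H[i + 1L, jj + 1L] <- gap * jj + cummax(vals)[jj + 1L]
  }
  # deterministic traceback: diagonal > up > left
  ref_base <- rep(NA_character_, n)
  ncols <- 0L
  nmatch <- 0L
  i <- n; j <- m
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    ncols <- ncols + 1L
    if (i > 0L && j > 0L &&
        abs(H[i + 1L, j + 1L] - (H[i, j] + sub_score(rc[i], cc[j]))) < eps) {
      ref_base[i] <- cc[j]
      if (sub_score(rc[i], cc[j]) == match) nmatch <- nmatch + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(H[i + 1L, j + 1L] - (H[i, j + 1L] + gap)) < eps) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  identity <- nmatch / ncols
  if (identity < min_identity)
    return(list(status = "discarded-unalignable", score = H[n + 1L, m + 1L],
                identity = identity, ref_base = rep(NA_character_, n)))
  list(status = "aligned", score = H[n + 1L, m + 1L], identity = identity,
       ref_base = ref_base)
}

#' Non-CpG conversion QC for DNA-mode clones
#'
#' In DNA bisulfite sequencing the cytosines outside CpG context are
#' (essentially) unmethylated, so their conversion rate measures the
#' clone's bisulfite conversion success: rate = T / (C + T) at non-CpG Cs.
#' Clones below `threshold` are flagged `discarded-incomplete`. With no
#' non-CpG C in the reference the QC is unavailable.
#'
#' @param ref_base_list list of `ref_base` vectors from [align_clone()]
#'   (one per clone, aligned clones only).
#' @param reference unconverted reference.
#' @param threshold minimum conversion rate, default 0.95.
#' @return data.frame: `clone`, `rate`, `pass`, `status`; or a list with
#'   `status = "unavailable"` when the reference has no non-CpG C.
#' @export
dna_conversion_qc <- function(ref_base_list, reference, threshold = 0.95) {
  cpg <- find_scored_positions(reference, "DNA-CpG")
  allc <- char_positions0(reference)
  noncpg <- setdiff(allc, cpg)
  if (length(noncpg) == 0L)
    return(list(status = "unavailable",
                reason = "reference has no non-CpG cytosine"))
  rows <- lapply(names(ref_base_list), function(id) {
    b <- ref_base_list[[id]][noncpg + 1L]
    nc <- sum(b == "C", na.rm = TRUE)
    nt <- sum(b == "T", na.rm = TRUE)
    rate <- if (nc + nt > 0L) nt / (nc + nt) else NA_real_
    data.frame(clone = id, rate = rate,
               pass = !is.na(rate) && rate >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$status <- ifelse(out$pass, "pass", "discarded-incomplete")
  out
}

#' Flag inconsistently placed cytosines and discard unconverted clones
#'
#' Operationalizes the rule that a cytosine whose methylation status is not
#' consistently placed across clones is an unconverted (false-positive)
#' call: a position's C-calls are flagged X when the position is observed
#' methylated in fewer than `min_recurrence` clones (default: 2 clones or
#' 20 % of clones, whichever is larger). A clone is `discarded-incomplete`
#' when the fraction of X among its C-calls exceeds
#' `clone_discard_fraction` (default 0.5) *and* it has at least
#' `min_x_calls` flagged calls (default 3) — the count floor keeps a single
#' stray unconverted cytosine from discarding an otherwise clean clone.
#'
#' @param states character matrix clones x scored positions with entries
#'   "M", "U" or NA (from [analyze_clones()] or simulator truth).
#' @param min_recurrence recurrence cutoff (count); NULL for the default
#'   `max(2, 0.2 * n_clones)`.
#' @param clone_discard_fraction X-fraction above which a clone is
#'   discarded.
#' @param min_x_calls minimum number of X calls for a discard.
#' @return list: `states` (with X), `verdicts` (named: "kept" or
#'   "discarded-incomplete"), `min_recurrence` used.
#' @export
flag_inconsistent <- function(states, min_recurrence = NULL,
                              clone_discard_fraction = 0.5, min_x_calls = 3L) {
  n <- nrow(states)
  if (is.null(min_recurrence)) min_recurrence <- max(2, 0.2 * n)
  m_count <- colSums(states == "M", na.rm = TRUE)
  flag_col <- m_count > 0L & m_count < min_recurrence
  out <- states
  for (j in which(flag_col)) out[states[, j] %in% "M", j] <- "X"
  c_calls <- rowSums(states == "M", na.rm = TRUE)
  x_calls <- rowSums(out == "X", na.rm = TRUE)
  discard <- c_calls > 0L & x_calls / pmax(c_calls, 1L) > clone_discard_fraction &
    x_calls >= min_x_calls
  verdicts <- stats::setNames(ifelse(discard, "discarded-incomplete", "kept"),
                              rownames(states))
  list(states = out, verdicts = verdicts, min_recurrence = min_recurrence)
}

#' Analyze a clone set: align, QC, flag, summarize
#'
#' Full clone pipeline for one region: aligns every clone to the reference
#' (bisulfite-aware), reads the M/U state at each scored position (M = C,
#' U = T, NA otherwise), applies the DNA-mode non-CpG conversion QC where
#' applicable, flags inconsistently placed cytosines, discards incomplete
#' clones, and computes per-position methylation percents over kept clones
#' (X and missing excluded). Fewer clones than the mode's minimum (8 for
#' DNA, 10 for RNA) triggers a low-confidence warning, not an abort.
#'
#' @param clones named character vector of clone sequences (or a
#'   `clone_set` from [clone_sequences()], whose reference and mode are then
#'   used).
#' @param reference unconverted reference (ignored for a `clone_set`).
#' @param mode `"DNA-CpG"` or `"RNA-anyC"` (ignored for a `clone_set`).
#' @param region_id region label.
#' @param min_clones minimum clone count; NULL for the mode default.
#' @param conversion_qc_threshold DNA-mode non-CpG conversion floor.
#' @param ... passed to [align_clone()] and [flag_inconsistent()]
#'   (`min_identity`, `min_recurrence`, `clone_discard_fraction`,
#'   `min_x_calls`).
#' @return list of class `clone_matrix`: `region_id`, `mode`, `positions`
#'   (0-based), `labels` (1-based), `states` (clones x positions:
#'   M/U/X/NA), `verdicts`, `percent` (per position, over kept clones),
#'   `n_kept`, `low_confidence`.
#' @export
analyze_clones <- function(clones, reference = NULL,
                           mode = c("RNA-anyC", "DNA-CpG"),
                           region_id = "region1", min_clones = NULL,
                           conversion_qc_threshold = 0.95, ...) {
  if (inherits(clones, "clone_set")) {
    reference <- clones$reference
    mode <- clones$mode
    region_id <- clones$region_id
    clones <- clones$clones
  } else {
    mode <- match.arg(mode)
  }
  if (is.null(names(clones)))
    names(clones) <- sprintf("clone%02d", seq_along(clones))
  if (is.null(min_clones)) min_clones <- if (mode == "DNA-CpG") 8L else 10L
  dots <- list(...)
  aln_args <- dots[names(dots) %in% c("match", "mismatch", "gap",
                                      "min_identity", "max_length_dev")]
  flag_args <- dots[names(dots) %in% c("min_recurrence",
                                       "clone_discard_fraction", "min_x_calls")]
  scored <- find_scored_positions(reference, mode)
  labels <- scored + 1L
  verdicts <- stats::setNames(rep("kept", length(clones)), names(clones))
  ref_bases <- list()
  for (id in names(clones)) {
    a <- do.call(align_clone, c(list(clones[[id]], reference), aln_args))
    if (a$status == "discarded-unalignable") {
      verdicts[id] <- "discarded-unalignable"
    } else {
      ref_bases[[id]] <- a$ref_base
    }
  }
  if (mode == "DNA-CpG" && length(ref_bases) > 0L) {
    qc <- dna_conversion_qc(ref_bases, reference,
                            threshold = conversion_qc_threshold)
    if (is.data.frame(qc)) {
      bad <- qc$clone[!qc$pass & !is.na(qc$rate)]
      verdicts[bad] <- "discarded-incomplete"
    }
  }
  cand <- names(verdicts)[verdicts == "kept"]
  states <- matrix(NA_character_, length(cand), length(scored),
                   dimnames = list(cand, as.character(labels)))
  for (id in cand) {
    b <- ref_bases[[id]][scored + 1L]
    states[id, ] <- ifelse(b %in% "C", "M", ifelse(b %in% "T", "U", NA))
  }
  low_confidence <- length(cand) < min_clones
  if (low_confidence)
    warning(sprintf("region '%s': only %d alignable clone(s), fewer than the minimum %d; results are low-confidence",
                    region_id, length(cand), min_clones), call. = FALSE)
  if (length(cand) > 0L && length(scored) > 0L) {
    fl <- do.call(flag_inconsistent, c(list(states), flag_args))
    states <- fl$states
    verdicts[names(fl$verdicts)[fl$verdicts != "kept"]] <- "discarded-incomplete"
  }
  kept <- rownames(states)[verdicts[rownames(states)] == "kept"]
  percent <- if (length(kept) > 0L && length(scored) > 0L) {
    ks <- states[kept, , drop = FALSE]
    nm <- colSums(ks == "M", na.rm = TRUE)
    nu <- colSums(ks == "U", na.rm = TRUE)
    ifelse(nm + nu > 0L, 100 * nm / (nm + nu), NA_real_)
  } else {
    rep(NA_real_, length(scored))
  }
  structure(list(region_id = region_id, mode = mode, positions = scored,
                 labels = labels, states = states, verdicts = verdicts,
                 percent = stats::setNames(percent, as.character(labels)),
                 n_kept = length(kept), low_confidence = low_confidence),
            class = "clone_matrix")
}

#' Summarize a clone matrix
#'
#' Per-position counts and methylation percents over kept clones, plus a
#' text lollipop rendering (one row per kept clone; filled circle = M, open
#' circle = U, dot = X or missing). Positions are labelled 1-based, the
#' way targeted loci are reported (e.g. C1324).
#'
#' @param cm a `clone_matrix` from [analyze_clones()].
#' @return list: `table` (data.frame pos, label, n_M, n_U, n_X, percent),
#'   `lollipop` (character vector of rendered rows), `n_kept`.
#' @export
summarize_clones <- function(cm) {
  kept <- rownames(cm$states)[cm$verdicts[rownames(cm$states)] == "kept"]
  if (length(kept) == 0L)
    return(list(table = data.frame(), lollipop = character(0), n_kept = 0L,
                reason = "zero kept clones"))
  ks <- cm$states[kept, , drop = FALSE]
  tab <- data.frame(pos = cm$positions, label = cm$labels,
                    n_M = colSums(ks == "M", na.rm = TRUE),
                    n_U = colSums(ks == "U", na.rm = TRUE),
                    n_X = colSums(ks == "X", na.rm = TRUE),
                    percent = unname(cm$percent), row.names = NULL)
  glyph <- function(s) ifelse(s %in% "M", "●",
                              ifelse(s %in% "U", "○", "·"))
  lolli <- vapply(kept, function(id)
    sprintf("%-10s %s", id, paste(glyph(ks[id, ]), collapse = " ")),
    character(1L))
  list(table = tab, lollipop = unname(lolli), n_kept = length(kept))
}
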