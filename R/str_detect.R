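# Substitution-only STR detector for periods 1-9, so the pipeline can run
# on raw (synthetic) sequence without a precomputed repeats table.
#
# Detection works on the period-p autocorrelation indicator
# m[i] = (s[i] == s[i-p]): exact-match runs of at least seed_len open a
# candidate, the candidate absorbs neighbouring runs while no mismatch run
# exceeds max_gap, and both ends are then trimmed to the span maximising
# match_weight * matches - mismatch_penalty * mismatches (the first period
# of a span always counts as matching its own consensus).

#' Configuration for the built-in repeat detector
#'
#' @param scoring A [scoring_params()] object (reporting thresholds).
#' @param seed_len Exact autocorrelation run needed to open a candidate;
#'   `NULL` means `max(12, 2 * period)` per period.
#' @param max_gap Longest run of autocorrelation mismatches tolerated inside
#'   a candidate; `NULL` means `period`.
#' @param report_min_purity Lowest purity a detector record may have. The
#'   default (80) sits below the table-membership filter (90) so that
#'   downstream purity filtering is observable.
#' @return A `detector_config` list.
#' @export
detector_config <- function(scoring = scoring_params(), seed_len = NULL,
                            max_gap = NULL, report_min_purity = 80) {
  if (!inherits(scoring, "scoring_params")) {
    stop("scoring must be a scoring_params object")
  }
  if (!is.null(max_gap) && max_gap < 0) stop("max_gap must be >= 0")
  structure(list(scoring = scoring, seed_len = seed_len, max_gap = max_gap,
                 report_min_purity = report_min_purity),
            class = "detector_config")
}

#' Scan one sequence for repeat candidates at a fixed period
#'
#' Returns candidate spans before consensus/purity computation and before
#' cross-period overlap resolution; [detect_strs()] is the user-facing entry
#' point.
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @param period Repeat-unit length, 1-9.
#' @param cfg A [detector_config()].
#' @return data.frame with 0-based `srStart`, exclusive `srEnd`, and `score`.
#' @export
scan_period <- function(sequence, period, cfg = detector_config()) {
  p <- as.integer(period)
  if (is.na(p) || p < 1 || p > 9) stop("period must be in 1..9")
  chars <- .dna_chars(sequence)
  n <- length(chars)
  empty <- data.frame(srStart = integer(0), srEnd = integer(0),
                      score = numeric(0))
  if (n < min_reportable_length(cfg$scoring)) return(empty)

  valid <- chars %in% VALID_BASES
  m <- logical(n)
  idx <- (p + 1L):n
  m[idx] <- chars[idx] == chars[idx - p] & valid[idx] & valid[idx - p]

  seed_len <- if (is.null(cfg$seed_len)) max(12L, 2L * p) else cfg$seed_len
  gap <- if (is.null(cfg$max_gap)) p else cfg$max_gap
  w <- cfg$scoring$match_weight
  pen <- cfg$scoring$mismatch_penalty

  r <- rle(m)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  n_runs <- length(r$lengths)
  # candidates grow around seed-length match runs; mismatch runs longer
  # than the tolerated gap bound the segment a candidate can occupy
  seeds <- which(r$values & r$lengths >= seed_len)
  if (length(seeds) == 0L) return(empty)
  big <- which(!r$values & r$lengths > gap)
  li <- findInterval(seeds, big)
  seg_left <- ifelse(li == 0L, 1L, big[pmax(li, 1L)] + 1L)
  seg_right <- ifelse(li + 1L > length(big), n_runs, big[pmin(li + 1L,
                                                length(big))] - 1L)
  # one candidate per segment, anchored at its longest seed run
  first <- !duplicated(seg_left)
  out <- vector("list", sum(first))
  oi <- 0L
  for (s in split(seq_along(seeds), seg_left)) {
    longest <- seeds[s][which.max(r$lengths[seeds[s]])]
    lo <- seg_left[s[1L]]
    hi <- seg_right[s[1L]]
    if (!r$values[lo]) lo <- lo + 1L
    if (!r$values[hi]) hi <- hi - 1L
    a <- run_start[lo]
    b <- run_end[hi]
    s1 <- run_start[longest]
    s2 <- run_end[longest]
    val <- ifelse(m[a:b], w, -pen)
    # optimal left/right extension of the anchor run within [a, b]
    x <- s1
    if (s1 > a) {
      pre <- rev(cumsum(rev(val[seq_len(s1 - a)])))
      if (max(pre) > 0) x <- a + which.max(pre) - 1L
    }
    y <- s2
    if (s2 < b) {
      suf <- cumsum(val[(s2 - a + 2L):(b - a + 1L)])
      if (max(suf) > 0) y <- s2 + which.max(suf)
    }
    score <- w * p + sum(val[(x - a + 1L):(y - a + 1L)])
    oi <- oi + 1L
    out[[oi]] <- data.frame(srStart = x - p - 1L, srEnd = y, score = score)
  }
  if (oi == 0L) return(empty)
  do.call(rbind, out[seq_len(oi)])
}

#' Smallest motif whose tiling reproduces a given motif
#'
#' Collapses non-primitive consensus calls, e.g. a period-4 "ACAC" to the
#' period-2 "AC". "CACCCC" is already primitive and is returned unchanged.
#'
#' @param motif Non-empty string.
#' @return The primitive motif.
#' @export
primitive_motif <- function(motif) {
  n <- nchar(motif)
  if (n == 0L) stop("motif must be non-empty")
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L) {
      unit <- substr(motif, 1L, d)
      if (paste(rep(unit, n / d), collapse = "") == motif) return(unit)
    }
  }
  motif
}

# Assemble a full repeat record for a candidate span.
.candidate_record <- function(chars, chrom, srStart0, srEnd0, period, score,
                              cfg) {
  tract <- chars[(srStart0 + 1L):srEnd0]
  consensus <- paste(.consensus_vote(tract, period, ignore_n = TRUE),
                     collapse = "")
  prim <- primitive_motif(consensus)
  if (nchar(prim) < period) {
    period <- nchar(prim)
    consensus <- prim
    score <- .span_score(chars, srStart0, srEnd0, period, cfg$scoring)
  }
  len <- srEnd0 - srStart0
  comp <- base_composition(paste(tract, collapse = ""))
  frac_n <- sum(tract %in% VALID_BASES)
  fracs <- if (frac_n > 0) {
    tabulate(match(tract[tract %in% VALID_BASES], VALID_BASES), 4L) / frac_n
  } else rep(0, 4)
  data.frame(chrom = chrom, srStart = srStart0, srEnd = srEnd0,
             period = as.integer(period),
             numRepeats = round_half_up(len / period, 1),
             consensusSize = nchar(consensus),
             perMatch = compute_purity(paste(tract, collapse = ""), consensus),
             perIndel = 0L, score = score,
             baseA = comp[["A"]], baseC = comp[["C"]], baseG = comp[["G"]],
             baseT = comp[["T"]],
             entropy = if (frac_n > 0) compute_entropy(fracs) else 0,
             sequence = consensus, stringsAsFactors = FALSE)
}

# Indel-free alignment score of the 0-based span [srStart0, srEnd0) at a
# given period: the first `period` bases count as matches.
.span_score <- function(chars, srStart0, srEnd0, period, params) {
  len <- srEnd0 - srStart0
  if (len <= period) return(params$match_weight * len)
  i <- (srStart0 + period + 1L):srEnd0
  valid <- chars %in% VALID_BASES
  mm <- chars[i] == chars[i - period] & valid[i] & valid[i - period]
  params$match_weight * (period + sum(mm)) -
    params$mismatch_penalty * sum(!mm)
}

# Keep the higher score, then the smaller period, then the leftmost record
# among records sharing >= `frac` of the shorter span.
.resolve_overlaps <- function(recs, frac = 0.5) {
  if (nrow(recs) <= 1L) return(recs)
  ord <- order(-recs$score, recs$period, recs$srStart)
  recs <- recs[ord, , drop = FALSE]
  keep <- logical(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    ks <- which(keep)
    if (length(ks) > 0L) {
      ov <- pmin(recs$srEnd[ks], recs$srEnd[i]) -
        pmax(recs$srStart[ks], recs$srStart[i])
      shorter <- pmin(recs$srEnd[ks] - recs$srStart[ks],
                      recs$srEnd[i] - recs$srStart[i])
      if (any(ov >= frac * shorter)) next
    }
    keep[i] <- TRUE
  }
  recs[keep, , drop = FALSE]
}

#' Detect short tandem repeats in one or more sequences
#'
#' Scans each sequence at periods 1-9, infers a consensus motif per
#' candidate (collapsed to its primitive period), computes purity,
#' composition and entropy, keeps records with score at or above
#' `min_score` and purity at or above `report_min_purity`, and resolves
#' overlapping calls that share at least half of the shorter span by score,
#' then smaller period, then leftmost position. Records carry `perIndel = 0`
#' (the detector is substitution-only).
#'
#' @param sequences Named character vector, a single string, or a
#'   `Biostrings::DNAStringSet`.
#' @param cfg A [detector_config()].
#' @return Repeat table sorted by (chrom, srStart); see
#'   [read_simple_repeats()] for the column set.
#' @export
detect_strs <- function(sequences, cfg = detector_config()) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  sequences <- unlist(sequences)
  if (length(sequences) == 0L) return(empty_str_records())
  if (is.null(names(sequences))) {
    names(sequences) <- if (length(sequences) == 1L) "seq" else
      paste0("seq", seq_along(sequences))
  }
  out <- list()
  for (chrom in names(sequences)) {
    chars <- .dna_chars(sequences[[chrom]])
    recs <- list()
    for (p in 1:9) {
      cands <- scan_period(sequences[[chrom]], p, cfg)
      for (j in seq_len(nrow(cands))) {
        recs[[length(recs) + 1L]] <- .candidate_record(
          chars, chrom, cands$srStart[j], cands$srEnd[j], p,
          cands$score[j], cfg)
      }
    }
    if (length(recs) == 0L) next
    recs <- do.call(rbind, recs)
    recs <- recs[recs$score >= cfg$scoring$min_score &
                   recs$perMatch >= cfg$report_min_purity &
                   recs$period <= cfg$scoring$max_period, , drop = FALSE]
    out[[chrom]] <- .resolve_overlaps(recs)
  }
  if (length(out) == 0L) return(empty_str_records())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$srStart), , drop = FALSE]
  rownames(res) <- NULL
  res
}
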