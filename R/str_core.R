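# Repeat-level data types and metrics: alignment score, minimum reportable
# tract length, consensus inference, purity, base composition and entropy.

VALID_BASES <- c("A", "C", "G", "T")

#' Scoring parameters for tandem-repeat reporting
#'
#' Bundles the scoring and filtering thresholds that govern which tandem
#' repeats are reported and which enter the regulatory-region table. The
#' per-base match weight of 2 and the minimum alignment score of 50 are the
#' values in force in the UCSC simpleRepeats track; together they imply a
#' minimum reportable tract of 25 bp. Mismatch and indel penalties default
#' to the Tandem Repeat Finder conventions (7/7) and only matter for the
#' built-in substitution-only detector.
#'
#' @param match_weight Score contributed by each base matching the consensus.
#' @param mismatch_penalty Score deducted per mismatching base.
#' @param indel_penalty Score deducted per inserted/deleted base (carried for
#'   completeness; the built-in detector is indel-free).
#' @param min_score Minimum alignment score for a repeat to be reported.
#' @param max_period Largest repeat-unit length that still counts as an STR.
#' @param min_purity Minimum percent match to consensus for table membership.
#' @return A `scoring_params` list.
#' @examples
#' p <- scoring_params()
#' min_reportable_length(p)  # 25
#' @export
scoring_params <- function(match_weight = 2, mismatch_penalty = 7,
                           indel_penalty = 7, min_score = 50,
                           max_period = 9, min_purity = 90) {
  vals <- c(match_weight = match_weight, mismatch_penalty = mismatch_penalty,
            indel_penalty = indel_penalty, min_score = min_score,
            max_period = max_period, min_purity = min_purity)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all scoring parameters must be non-negative finite numbers")
  }
  if (max_period < 1) stop("max_period must be >= 1")
  structure(as.list(vals), class = "scoring_params")
}

#' Alignment score of a perfectly pure repeat tract
#'
#' Every base of a pure tract matches its consensus, so the score is simply
#' `match_weight * length`. A 39 bp pure dinucleotide tract (19.5 copies)
#' scores 78 at the default weight of 2.
#'
#' @param length_bp Tract length(s) in bp.
#' @param params A [scoring_params()] object.
#' @return Numeric score(s).
#' @export
pure_repeat_score <- function(length_bp, params = scoring_params()) {
  if (any(!is.finite(length_bp)) || any(length_bp < 0)) {
    stop("length_bp must be non-negative")
  }
  params$match_weight * length_bp
}

#' Minimum tract length a repeat can have and still be reported
#'
#' The smallest length at which a pure repeat reaches `min_score`:
#' `ceiling(min_score / match_weight)`. At the defaults (50, 2) this is
#' 25 bp, the floor observed in the simpleRepeats track.
#'
#' @param params A [scoring_params()] object.
#' @return Integer length in bp.
#' @export
min_reportable_length <- function(params = scoring_params()) {
  if (params$match_weight <= 0) {
    stop("match_weight must be positive to derive a minimum length")
  }
  as.integer(ceiling(params$min_score / params$match_weight))
}

.dna_chars <- function(x) {
  strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1]]
}

# Majority vote per period-phased column; ties go to the alphabetically
# first base. Non-ACGT characters are dropped from the vote when ignore_n.
.consensus_vote <- function(chars, period, ignore_n = FALSE) {
  n <- length(chars)
  vapply(seq_len(period), function(j) {
    col <- chars[seq(j, n, by = period)]
    if (ignore_n) col <- col[col %in% VALID_BASES]
    if (length(col) == 0L) return("A")
    tab <- table(factor(col, levels = VALID_BASES))
    names(tab)[which.max(tab)]  # which.max keeps the first (alphabetical) max
  }, character(1))
}

#' Infer the consensus motif of a repeat tract
#'
#' Column-wise majority vote over the period-phased columns of the tract
#' (column j collects positions j, j+period, ...). Ties break alphabetically
#' (A < C < G < T).
#'
#' @param tract DNA string over A/C/G/T.
#' @param period Repeat-unit length, `1 <= period <= nchar(tract)`.
#' @return Consensus motif of length `period`.
#' @examples
#' infer_consensus("ACGACGACT", 3)  # "ACG"
#' @export
infer_consensus <- function(tract, period) {
  chars <- .dna_chars(tract)
  n <- length(chars)
  if (period < 1 || period > n) stop("period must be in [1, nchar(tract)]")
  if (!all(chars %in% VALID_BASES)) {
    stop("tract contains non-ACGT characters")
  }
  paste(.consensus_vote(chars, as.integer(period)), collapse = "")
}

#' Percent match of a tract to a tiled consensus motif
#'
#' Tiles the motif across the tract at each of the `nchar(motif)` possible
#' phases (no indels) and returns 100 x matches / length for the best phase,
#' rounded to the nearest integer. `N` bases never match.
#'
#' @param tract DNA string (A/C/G/T/N).
#' @param motif Non-empty consensus motif over A/C/G/T.
#' @return Integer purity percentage in \[0, 100\].
#' @examples
#' compute_purity("AAAAAAAAAT", "A")  # 90
#' @export
compute_purity <- function(tract, motif) {
  chars <- .dna_chars(tract)
  n <- length(chars)
  if (n == 0L) stop("tract must be non-empty")
  mo <- .dna_chars(motif)
  m <- length(mo)
  if (m == 0L) stop("motif must be non-empty")
  best <- 0L
  for (k in seq_len(m) - 1L) {
    tiled <- mo[((seq_len(n) - 1L + k) %% m) + 1L]
    best <- max(best, sum(chars == tiled))
  }
  as.integer(round_half_up(100 * best / n))
}

#' Base composition of a tract as truncated integer percentages
#'
#' Percent of A, C, G and T over the tract, truncated to integers (so the
#' four values sum to at most 100 and at least 97). `N` bases are excluded
#' from both numerator and denominator.
#'
#' @param tract Non-empty DNA string.
#' @return Named integer vector `c(A=, C=, G=, T=)`.
#' @export
base_composition <- function(tract) {
  chars <- .dna_chars(tract)
  if (length(chars) == 0L) stop("tract must be non-empty")
  chars <- chars[chars %in% VALID_BASES]
  denom <- length(chars)
  if (denom == 0L) {
    return(c(A = 0L, C = 0L, G = 0L, T = 0L))
  }
  counts <- table(factor(chars, levels = VALID_BASES))
  out <- as.integer(floor(100 * as.integer(counts) / denom))
  names(out) <- VALID_BASES
  out
}

#' Shannon entropy of a base-composition vector
#'
#' `-sum(p * log2(p))` over the positive entries; 0 for a homopolymer, 2 bits
#' at uniform composition.
#'
#' @param p Numeric vector of base fractions summing to ~1.
#' @return Entropy in bits, in \[0, 2\] for 4-letter compositions.
#' @export
compute_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || any(p > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(p) - 1) > 0.01) stop("fractions must sum to ~1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Round-half-up (Table-style rounding: 12.65 -> 12.7, not banker's).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Zero-row repeat table with the canonical column set and types.
empty_str_records <- function() {
  data.frame(chrom = character(0), srStart = integer(0), srEnd = integer(0),
             period = integer(0), numRepeats = numeric(0),
             consensusSize = integer(0), perMatch = integer(0),
             perIndel = integer(0), score = numeric(0),
             baseA = integer(0), baseC = integer(0), baseG = integer(0),
             baseT = integer(0), entropy = numeric(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

# Validate a repeat table against the type invariants; returns indices of
# rows that pass, messaging a reason for each rejected row.
validate_str_records <- function(df, context = "record") {
  ok <- rep(TRUE, nrow(df))
  reason <- character(nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[cond & ok] <<- why
    ok <<- ok & !cond
  }
  bad(df$srEnd <= df$srStart, "srEnd must exceed srStart")
  bad(df$perMatch < 0 | df$perMatch > 100, "perMatch outside [0, 100]")
  bad(df$perIndel < 0 | df$perIndel > 100, "perIndel outside [0, 100]")
  bad(df$entropy < 0 | df$entropy > 2 + 1e-9, "entropy outside [0, 2]")
  bad(df$period < 1, "period must be >= 1")
  if (any(!ok)) {
    for (i in which(!ok)) {
      message(sprintf("rejected %s %d: %s", context, i, reason[i]))
    }
  }
  which(ok)
}

# Internal guard used by modules that require an RNG-reproducible block:
# runs `code` under `seed` and restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
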