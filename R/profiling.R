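# Per-base TSS-relative profiles: coverage counts, density, period
# decomposition, composition/copy-number means, LOWESS smoothing, period
# spectra and CpG-island stratification.

.profile_grid <- function(up, down) seq.int(-up, down - 1L)

#' Per-position repeat coverage across the TSS window
#'
#' Each table row adds 1 to every TxPos position it covers,
#' `[txPos, txPos + srLength - 1]`. The total equals the summed tract
#' lengths (conservation), which is checked downstream.
#'
#' @param rows Table rows with `txPos` and `srLength`.
#' @param up,down Window extent in bp.
#' @return Named integer vector over positions `-up .. down-1`.
#' @export
position_counts <- function(rows, up = 2000, down = 1000) {
  npos <- up + down
  if (nrow(rows) > 0 &&
      (any(rows$txPos < -up) || any(rows$txPos + rows$srLength > down))) {
    stop("row violates full containment in the [-up, down) window")
  }
  delta <- numeric(npos + 1L)
  if (nrow(rows) > 0) {
    i0 <- rows$txPos + up + 1L
    for (j in seq_len(nrow(rows))) {
      delta[i0[j]] <- delta[i0[j]] + 1
      delta[i0[j] + rows$srLength[j]] <- delta[i0[j] + rows$srLength[j]] - 1
    }
  }
  counts <- as.integer(cumsum(delta[seq_len(npos)]))
  names(counts) <- .profile_grid(up, down)
  counts
}

#' Normalise coverage counts to a per-region density
#'
#' @param counts Output of [position_counts()].
#' @param n_regions Number of regulatory regions profiled; must be > 0.
#' @return Numeric density vector.
#' @export
to_density <- function(counts, n_regions) {
  if (length(n_regions) != 1L || !is.finite(n_regions) || n_regions <= 0) {
    stop("n_regions must be a single positive number")
  }
  counts / n_regions
}

#' LOWESS smoothing of a positional series
#'
#' Locally weighted linear regression with tricube weights, applied on the
#' position grid. Robustness iterations are available but default to 0:
#' coverage profiles are spiky by nature and the robust reweighting treats
#' genuine peaks as outliers, visibly deflating the curve (and its mean).
#' Positions that are `NA` (uncovered, in mean profiles) are left `NA`
#' and excluded from the fit.
#'
#' @param series Numeric vector.
#' @param frac Smoother span as a fraction of the data, in (0, 1\].
#' @param iters Robustness iterations (0 = plain local regression).
#' @param x Optional positions (defaults to the index).
#' @return Smoothed vector on the same grid.
#' @export
lowess_smooth <- function(series, frac = 0.1, iters = 0, x = NULL) {
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  if (is.null(x)) x <- seq_along(series)
  ok <- !is.na(series)
  if (sum(ok) < 3L) {
    warning("series shorter than 3 points; returned unchanged")
    return(series)
  }
  out <- series
  fit <- stats::lowess(x[ok], series[ok], f = frac, iter = iters)
  # x is strictly increasing here, so lowess preserves the ordering
  out[ok] <- fit$y
  out
}

#' Coverage profiles split by repeat period
#'
#' @param rows Table rows.
#' @param up,down Window extent.
#' @return 9 x (up+down) matrix, row `p` holding the period-`p` counts;
#'   columns sum to [position_counts()] at every position.
#' @export
decompose_by_period <- function(rows, up = 2000, down = 1000) {
  mat <- t(vapply(1:9, function(p) {
    position_counts(rows[rows$Period == p, , drop = FALSE], up, down)
  }, numeric(up + down)))
  rownames(mat) <- paste0("period", 1:9)
  mat
}

#' Mean base composition and copy number per TxPos position
#'
#' At each position the unweighted mean over covering rows of the
#' repeat-level A/C/G/T percentages and of the copy number. Positions with
#' zero coverage are `NA` (missing, not zero), which keeps uncovered
#' stretches from dragging the composition curves toward zero.
#'
#' @param rows Table rows.
#' @param up,down Window extent.
#' @return List with `meanBasePct` (4 x npos matrix, rows A/C/G/T),
#'   `meanNumRepeats` and `coverage`.
#' @export
composition_profile <- function(rows, up = 2000, down = 1000) {
  npos <- up + down
  sums <- matrix(0, nrow = 5L, ncol = npos,
                 dimnames = list(c("A", "C", "G", "T", "numRepeats"), NULL))
  cover <- numeric(npos)
  if (nrow(rows) > 0) {
    for (j in seq_len(nrow(rows))) {
      idx <- (rows$txPos[j] + up + 1L):(rows$txPos[j] + up + rows$srLength[j])
      cover[idx] <- cover[idx] + 1
      sums["A", idx] <- sums["A", idx] + rows$A[j]
      sums["C", idx] <- sums["C", idx] + rows$C[j]
      sums["G", idx] <- sums["G", idx] + rows$G[j]
      sums["T", idx] <- sums["T", idx] + rows$T[j]
      sums["numRepeats", idx] <- sums["numRepeats", idx] + rows$numRepeats[j]
    }
  }
  denom <- ifelse(cover > 0, cover, NA_real_)
  means <- sweep(sums, 2L, denom, "/")
  grid <- .profile_grid(up, down)
  colnames(means) <- grid
  names(cover) <- grid
  list(meanBasePct = means[c("A", "C", "G", "T"), , drop = FALSE],
       meanNumRepeats = means["numRepeats", ],
       coverage = cover)
}

#' Period spectrum of repeat sets, by compartment
#'
#' For each compartment, the fraction of member repeats at each period
#' 1..9; fractions sum to 1 for non-empty compartments. Membership is
#' whatever the caller supplies (typically any-overlap subsets via
#' [overlaps_entity()] / [classify_compartments()]); an empty compartment
#' yields an all-`NA` row with a logged note.
#'
#' @param strs Repeat table with a `period` (or `Period`) column.
#' @param compartment_sets Named list; each element is a logical or integer
#'   index into `strs`. `NULL` profiles all repeats as one set named "all".
#' @return Matrix (compartments x periods 1..9) of proportions.
#' @export
period_spectrum <- function(strs, compartment_sets = NULL) {
  period <- if ("period" %in% names(strs)) strs$period else strs$Period
  if (is.null(compartment_sets)) {
    compartment_sets <- list(all = seq_along(period))
  }
  mat <- t(vapply(names(compartment_sets), function(nm) {
    p <- period[compartment_sets[[nm]]]
    if (length(p) == 0L) {
      message(sprintf("compartment '%s' is empty", nm))
      return(rep(NA_real_, 9L))
    }
    tabulate(p, nbins = 9L) / length(p)
  }, numeric(9L)))
  colnames(mat) <- as.character(1:9)
  mat
}

#' Partition table rows by their region's CpG-island flag
#'
#' @param rows Table rows (matched to regions by `refSeqId`).
#' @param regions CpG-flagged regions from [flag_cpg_overlap()].
#' @return List `cpg_rows` / `noncpg_rows`; an exhaustive, disjoint
#'   partition of `rows`.
#' @export
split_by_cpg <- function(rows, regions) {
  flag <- regions$cpgOverlap[match(rows$refSeqId, regions$transcriptId)]
  if (any(is.na(flag))) stop("rows reference transcripts absent from regions")
  list(cpg_rows = rows[flag, , drop = FALSE],
       noncpg_rows = rows[!flag, , drop = FALSE])
}
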