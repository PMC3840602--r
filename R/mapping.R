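# Joining repeats to regulatory regions: TSS-relative coordinates,
# containment and overlap rules, compartment classification and
# construction of the final annotation table.

STARRRT_COLS <- c("Chrom", "chromStart", "chromEnd", "cdsStart", "cdsEnd",
                  "Strand", "knownGeneId", "refSeqId", "ensGeneId",
                  "sourceAcc", "hgncSymbol", "U133Id", "U133Plus2Id",
                  "Category", "txPos", "srStart", "srEnd", "Period",
                  "numRepeats", "srLength", "consensusSize", "perMatch",
                  "perIndel", "Score", "A", "C", "G", "T", "Entropy",
                  "Sequence")

# TxPos-space promoter windows (closed intervals).
COMPARTMENT_WINDOWS <- list(upstream = c(-2000, -1),
                            proximal_promoter = c(-250, 250),
                            core_promoter = c(-60, 40),
                            regulatory_region = c(-2000, 1000))

#' TSS-relative start coordinate of a repeat
#'
#' In transcript orientation: `srStart - txStart` on the plus strand and
#' `txEnd - srEnd` on the minus strand. Negative values lie upstream of
#' the TSS.
#'
#' @param str Repeat row(s): data.frame or list with `chrom`, `srStart`,
#'   `srEnd`.
#' @param gene Gene row(s): data.frame or list with `chrom`, `strand`,
#'   `txStart`, `txEnd`. Either argument may be length one and is recycled.
#' @return Numeric TxPos value(s).
#' @examples
#' tx_pos(list(chrom = "chr1", srStart = 1101897, srEnd = 1101928),
#'        list(chrom = "chr1", strand = "+", txStart = 1102483,
#'             txEnd = 1102578))  # -586
#' @export
tx_pos <- function(str, gene) {
  if (any(str$chrom != gene$chrom)) {
    stop("repeat and gene must lie on the same chromosome")
  }
  ifelse(gene$strand == "+", str$srStart - gene$txStart,
         gene$txEnd - str$srEnd)
}

#' Full-containment test against a regulatory window
#'
#' Table membership requires both repeat endpoints inside the window:
#' `srStart >= windowStart` and `srEnd <= windowEnd`.
#'
#' @param str Repeat row(s) with `chrom`, `srStart`, `srEnd`.
#' @param region Region row(s) with `chrom`, `windowStart`, `windowEnd`.
#' @return Logical vector.
#' @export
contained_in_regulatory <- function(str, region) {
  str$chrom == region$chrom &
    str$srStart >= region$windowStart & str$srEnd <= region$windowEnd
}

#' Any-overlap test of a repeat against an interval set
#'
#' A repeat qualifies as located within an entity (exon, intron, 5'-UTR,
#' promoter window) if some portion of it overlaps: at least 1 bp of
#' half-open intersection.
#'
#' @param str A repeat row with `srStart`, `srEnd`.
#' @param intervals data.frame with half-open `start`/`end` columns.
#' @return `TRUE` if any interval intersects.
#' @export
overlaps_entity <- function(str, intervals) {
  if (nrow(intervals) == 0L) return(FALSE)
  any(str$srStart < intervals$end & intervals$start < str$srEnd)
}

#' Compartment labels for a mapped repeat
#'
#' Promoter labels (`upstream` \[-2000, -1\], `proximal_promoter`
#' \[-250, +250\], `core_promoter` \[-60, +40\], `regulatory_region`
#' \[-2000, +1000\]) are assigned by overlap of the closed TxPos span
#' `[txPos, txPos + srLength - 1]` with each closed window. Genic labels
#' (`exon`, `intron`, `five_prime_utr`) use genomic any-overlap against
#' [gene_compartments()]. Labels are not exclusive.
#'
#' @param txPos TSS-relative start of the repeat.
#' @param srLength Repeat tract length in bp.
#' @param gene Optional single gene-model row for genic labels.
#' @param srStart,srEnd Genomic repeat coordinates (required with `gene`).
#' @return Character vector of labels.
#' @export
classify_compartments <- function(txPos, srLength, gene = NULL,
                                  srStart = NULL, srEnd = NULL) {
  lo <- txPos
  hi <- txPos + srLength - 1
  labels <- names(COMPARTMENT_WINDOWS)[vapply(COMPARTMENT_WINDOWS,
    function(wdw) lo <= wdw[2] && wdw[1] <= hi, logical(1))]
  if (!is.null(gene)) {
    comp <- gene_compartments(gene)
    s <- list(srStart = srStart, srEnd = srEnd)
    if (overlaps_entity(s, comp$fiveUTR)) labels <- c(labels, "five_prime_utr")
    if (overlaps_entity(s, comp$exons)) labels <- c(labels, "exon")
    if (overlaps_entity(s, comp$introns)) labels <- c(labels, "intron")
  }
  labels
}

#' Build the regulatory-region repeat table
#'
#' Filters the input repeats to STRs (period <= `max_period`) with purity
#' at or above `min_purity`, then emits one row per (repeat, region) pair
#' where the repeat is fully contained in the region's window. A repeat
#' inside two genes' windows yields two rows. Rows follow the fixed
#' 30-column layout (see [write_starrrt()]) and are sorted by
#' (Chrom, chromStart, srStart). Per-stage filter counts are attached as
#' `attr(x, "counts")`.
#'
#' @param strs Repeat table ([detect_strs()] or [read_simple_repeats()]).
#' @param regions Regions from [regulatory_window()] (optionally CpG
#'   flagged).
#' @param params A [scoring_params()] (supplies `max_period`, `min_purity`).
#' @param id_map Optional data.frame keyed by `refSeqId` supplying
#'   `knownGeneId`, `ensGeneId`, `sourceAcc`, `U133Id`, `U133Plus2Id`;
#'   unmapped identifier columns are emitted empty.
#' @return data.frame of table rows.
#' @export
build_starrrt <- function(strs, regions, params = scoring_params(),
                          id_map = NULL) {
  n_input <- nrow(strs)
  strs <- strs[strs$perMatch >= params$min_purity, , drop = FALSE]
  n_purity <- nrow(strs)
  strs <- strs[strs$period <= params$max_period, , drop = FALSE]
  n_period <- nrow(strs)

  rows <- NULL
  if (n_period > 0L && nrow(regions) > 0L) {
    str_gr <- GenomicRanges::GRanges(
      strs$chrom, IRanges::IRanges(strs$srStart + 1L, strs$srEnd))
    reg_gr <- GenomicRanges::GRanges(
      regions$chrom,
      IRanges::IRanges(regions$windowStart + 1L, regions$windowEnd))
    hits <- GenomicRanges::findOverlaps(str_gr, reg_gr, type = "within")
    si <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    if (length(si) > 0L) {
      txPos <- tx_pos(strs[si, , drop = FALSE], regions[ri, , drop = FALSE])
      ids <- function(col) {
        if (!is.null(id_map) && col %in% names(id_map)) {
          v <- id_map[[col]][match(regions$transcriptId[ri], id_map$refSeqId)]
          ifelse(is.na(v), "", v)
        } else rep("", length(si))
      }
      rows <- data.frame(
        Chrom = strs$chrom[si],
        chromStart = regions$txStart[ri],
        chromEnd = regions$txEnd[ri],
        cdsStart = regions$cdsStart[ri],
        cdsEnd = regions$cdsEnd[ri],
        Strand = regions$strand[ri],
        knownGeneId = ids("knownGeneId"),
        refSeqId = regions$transcriptId[ri],
        ensGeneId = ids("ensGeneId"),
        sourceAcc = ids("sourceAcc"),
        hgncSymbol = regions$geneSymbol[ri],
        U133Id = ids("U133Id"),
        U133Plus2Id = ids("U133Plus2Id"),
        Category = regions$category[ri],
        txPos = txPos,
        srStart = strs$srStart[si],
        srEnd = strs$srEnd[si],
        Period = strs$period[si],
        numRepeats = strs$numRepeats[si],
        srLength = strs$srEnd[si] - strs$srStart[si],
        consensusSize = strs$consensusSize[si],
        perMatch = strs$perMatch[si],
        perIndel = strs$perIndel[si],
        Score = strs$score[si],
        A = strs$baseA[si],
        C = strs$baseC[si],
        G = strs$baseG[si],
        T = strs$baseT[si],
        Entropy = strs$entropy[si],
        Sequence = strs$sequence[si],
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(rows)) {
    rows <- as.data.frame(
      setNames(rep(list(character(0)), length(STARRRT_COLS)), STARRRT_COLS),
      stringsAsFactors = FALSE)
  }
  rows <- rows[order(rows$Chrom, rows$chromStart, rows$srStart), ,
               drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "counts") <- c(input = n_input, after_purity = n_purity,
                            after_period = n_period, rows = nrow(rows))
  rows
}
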