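# Gene-model ingestion, canonical-transcript selection, strand-aware
# TSS windows and genic compartments. All coordinates are 0-based
# half-open, the genePred convention.

GENE_COLS <- c("transcriptId", "chrom", "strand", "txStart", "txEnd",
               "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds",
               "geneSymbol")

#' Read a genePred-like gene table
#'
#' Expects tab-separated columns: name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds and an optional gene
#' symbol (falls back to the transcript name). Exon lists are
#' comma-separated. Rows violating the model invariants (txStart < txEnd,
#' CDS inside the transcript, sorted non-overlapping exons inside the
#' transcript) are dropped with a logged reason; malformed coordinates are
#' a parse error naming the offending line.
#'
#' @param path Path to the table; a `#`-prefixed or named header is allowed.
#' @return data.frame of gene models with list-columns `exonStarts`,
#'   `exonEnds` and a `category` column (`coding`/`noncoding`,
#'   noncoding iff cdsStart == cdsEnd).
#' @export
read_gene_table <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) return(empty_gene_models())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # a header row is recognised by a non-numeric txStart field
  if (suppressWarnings(is.na(as.numeric(fields[[1L]][4L])))) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 10L) {
      stop(sprintf("line %d: expected >= 10 tab-separated fields, got %d",
                   line_no[i], length(f)))
    }
    num <- suppressWarnings(as.numeric(f[4:8]))
    es <- suppressWarnings(as.numeric(strsplit(f[9L], ",", fixed = TRUE)[[1L]]))
    ee <- suppressWarnings(as.numeric(strsplit(f[10L], ",", fixed = TRUE)[[1L]]))
    if (any(is.na(num)) || any(is.na(es)) || any(is.na(ee))) {
      stop(sprintf("line %d: malformed coordinate field", line_no[i]))
    }
    rows[[i]] <- list(transcriptId = f[1L], chrom = f[2L], strand = f[3L],
                      txStart = num[1L], txEnd = num[2L],
                      cdsStart = num[3L], cdsEnd = num[4L],
                      exonStarts = es, exonEnds = ee,
                      geneSymbol = if (length(f) >= 11L && nzchar(f[11L]))
                        f[11L] else f[1L],
                      line = line_no[i])
  }
  gene_models(rows)
}

#' Build a validated gene-model table from parsed rows
#'
#' Accepts a list of row lists (as produced internally by
#' [read_gene_table()] or by the simulator) and applies the model
#' invariants, dropping offending rows with a logged reason.
#'
#' @param rows List of lists with the gene-model fields.
#' @return Validated gene-model data.frame.
#' @export
gene_models <- function(rows) {
  if (length(rows) == 0L) return(empty_gene_models())
  ok <- logical(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    where <- if (!is.null(r$line)) sprintf("line %d", r$line) else
      sprintf("row %d", i)
    reason <- NULL
    if (!(r$strand %in% c("+", "-"))) {
      reason <- "strand must be + or -"
    } else if (r$txStart >= r$txEnd) {
      reason <- "txStart must be < txEnd"
    } else if (r$cdsStart > r$cdsEnd || r$cdsStart < r$txStart ||
               r$cdsEnd > r$txEnd) {
      reason <- "CDS bounds must satisfy txStart <= cdsStart <= cdsEnd <= txEnd"
    } else if (length(r$exonStarts) != length(r$exonEnds) ||
               length(r$exonStarts) == 0L) {
      reason <- "exon start/end lists must be non-empty and parallel"
    } else if (any(r$exonEnds <= r$exonStarts) ||
               is.unsorted(r$exonStarts, strictly = TRUE) ||
               any(r$exonStarts[-1L] < r$exonEnds[-length(r$exonEnds)]) ||
               r$exonStarts[1L] < r$txStart ||
               r$exonEnds[length(r$exonEnds)] > r$txEnd) {
      reason <- "exons must be sorted, non-overlapping and within the transcript"
    }
    if (is.null(reason)) {
      ok[i] <- TRUE
    } else {
      message(sprintf("rejected gene model (%s, %s): %s",
                      rows[[i]]$transcriptId, where, reason))
    }
  }
  rows <- rows[ok]
  if (length(rows) == 0L) return(empty_gene_models())
  df <- data.frame(
    transcriptId = vapply(rows, `[[`, character(1), "transcriptId"),
    geneSymbol = vapply(rows, `[[`, character(1), "geneSymbol"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    txStart = vapply(rows, `[[`, numeric(1), "txStart"),
    txEnd = vapply(rows, `[[`, numeric(1), "txEnd"),
    cdsStart = vapply(rows, `[[`, numeric(1), "cdsStart"),
    cdsEnd = vapply(rows, `[[`, numeric(1), "cdsEnd"),
    stringsAsFactors = FALSE)
  df$exonStarts <- lapply(rows, `[[`, "exonStarts")
  df$exonEnds <- lapply(rows, `[[`, "exonEnds")
  df$category <- ifelse(df$cdsStart == df$cdsEnd, "noncoding", "coding")
  df
}

empty_gene_models <- function() {
  df <- data.frame(transcriptId = character(0), geneSymbol = character(0),
                   chrom = character(0), strand = character(0),
                   txStart = numeric(0), txEnd = numeric(0),
                   cdsStart = numeric(0), cdsEnd = numeric(0),
                   stringsAsFactors = FALSE)
  df$exonStarts <- list()
  df$exonEnds <- list()
  df$category <- character(0)
  df
}

#' Drop gene models on haplotype, random or unplaced contigs
#'
#' Removes models whose chromosome name contains an underscore, the UCSC
#' naming convention for haplotypic regions and unplaced contigs (for
#' example `chr6_cox_hap2`, `chrUn_gl000220`).
#'
#' @param genes Gene-model data.frame.
#' @return Filtered gene-model data.frame.
#' @export
exclude_nonprimary <- function(genes) {
  genes[!grepl("_", genes$chrom, fixed = TRUE), , drop = FALSE]
}

#' Select one canonical transcript per gene locus
#'
#' Loci are grouped by `geneSymbol`. If `canonical_ids` is supplied, the
#' listed transcript wins; otherwise the transcript with the longest genomic
#' span (txEnd - txStart) does, ties broken by the lexicographically
#' smallest transcript identifier. The result is deterministic and
#' independent of input row order.
#'
#' @param genes Gene-model data.frame.
#' @param canonical_ids Optional character vector of transcript identifiers.
#' @return One gene model per locus, sorted by (chrom, txStart, transcriptId).
#' @export
select_canonical <- function(genes, canonical_ids = NULL) {
  if (nrow(genes) == 0L) return(genes)
  if (!is.null(canonical_ids)) {
    missing <- setdiff(canonical_ids, genes$transcriptId)
    if (length(missing) > 0L) {
      warning(sprintf(
        "%d canonical id(s) absent from the gene table (e.g. %s); falling back to longest span for their loci",
        length(missing), missing[1L]))
    }
  }
  pick <- unlist(lapply(split(seq_len(nrow(genes)), genes$geneSymbol),
                        function(idx) {
    listed <- idx[genes$transcriptId[idx] %in% canonical_ids]
    if (length(listed) > 0L) {
      return(listed[order(genes$transcriptId[listed])][1L])
    }
    span <- genes$txEnd[idx] - genes$txStart[idx]
    cand <- idx[span == max(span)]
    cand[order(genes$transcriptId[cand])][1L]
  }), use.names = FALSE)
  out <- genes[pick, , drop = FALSE]
  out <- out[order(out$chrom, out$txStart, out$transcriptId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build strand-aware regulatory windows around each TSS
#'
#' The window spans `up` bp upstream to `down` bp downstream of the TSS in
#' transcript orientation: `[txStart - up, txStart + down)` on the plus
#' strand and `[txEnd - down, txEnd + up)` on the minus strand, clamped to
#' the chromosome when lengths are provided. Gene coordinate fields are
#' carried along so the table builder can emit them.
#'
#' @param genes Gene-model data.frame (one row per locus).
#' @param up,down Window extent in bp (defaults 2000 and 1000).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clamping.
#' @return data.frame of regions with `tss`, `windowStart`, `windowEnd` and
#'   a `cpgOverlap` flag initialised to `FALSE`.
#' @export
regulatory_window <- function(genes, up = 2000, down = 1000,
                              chrom_lengths = NULL) {
  if (up < 0 || down < 0) stop("up and down must be >= 0")
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$txStart, genes$txEnd)
  ws <- ifelse(plus, genes$txStart - up, genes$txEnd - down)
  we <- ifelse(plus, genes$txStart + down, genes$txEnd + up)
  ws <- pmax(ws, 0)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    we <- pmin(we, ifelse(is.na(lim), we, lim))
  }
  out <- genes
  out$tss <- tss
  out$windowStart <- ws
  out$windowEnd <- we
  out$cpgOverlap <- rep(FALSE, nrow(genes))
  out
}

# Intersect a set of half-open intervals with [lo, hi).
.clip_intervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo)
  e <- pmin(ends, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Exon, intron and 5'-UTR intervals of a gene model
#'
#' Introns are the gaps between consecutive exons; the 5'-UTR is the exonic
#' sequence strictly between the TSS and the CDS start in transcript
#' orientation (empty for noncoding models). Interval widths satisfy
#' sum(exons) + sum(introns) = txEnd - txStart.
#'
#' @param gene A single gene-model row.
#' @return List of data.frames `exons`, `introns`, `fiveUTR`, each with
#'   0-based half-open `start`/`end` columns.
#' @export
gene_compartments <- function(gene) {
  es <- unlist(gene$exonStarts)
  ee <- unlist(gene$exonEnds)
  exons <- data.frame(start = es, end = ee)
  k <- length(es)
  introns <- if (k >= 2L) {
    data.frame(start = ee[-k], end = es[-1L])
  } else data.frame(start = numeric(0), end = numeric(0))
  five <- if (gene$category == "noncoding") {
    data.frame(start = numeric(0), end = numeric(0))
  } else if (gene$strand == "+") {
    .clip_intervals(es, ee, gene$txStart, gene$cdsStart)
  } else {
    .clip_intervals(es, ee, gene$cdsEnd, gene$txEnd)
  }
  list(exons = exons, introns = introns, fiveUTR = five)
}

#' Read a BED3(+) file of CpG-island intervals
#'
#' @param path Path to a tab-separated BED file (no header; `#` comments
#'   and `track` lines skipped).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_cpg_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[[`, character(1), 1L),
             start = as.numeric(vapply(f, `[[`, character(1), 2L)),
             end = as.numeric(vapply(f, `[[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Flag regulatory regions that overlap a CpG island
#'
#' A region is flagged when any island interval intersects its window by at
#' least 1 bp (half-open overlap). With no islands supplied all flags are
#' `FALSE` and a note is logged.
#'
#' @param regions Output of [regulatory_window()].
#' @param islands data.frame with `chrom`, `start`, `end`, or `NULL`.
#' @return `regions` with `cpgOverlap` set.
#' @export
flag_cpg_overlap <- function(regions, islands = NULL) {
  if (is.null(islands) || nrow(islands) == 0L) {
    message("no CpG islands supplied; all cpgOverlap flags FALSE")
    regions$cpgOverlap <- rep(FALSE, nrow(regions))
    return(regions)
  }
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$windowStart + 1L, regions$windowEnd))
  isl_gr <- GenomicRanges::GRanges(
    islands$chrom, IRanges::IRanges(islands$start + 1L, islands$end))
  regions$cpgOverlap <- IRanges::overlapsAny(reg_gr, isl_gr)
  regions
}
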