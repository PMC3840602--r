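# A small two-gene fixture on one chromosome: a plus-strand and a
# minus-strand gene whose windows overlap, plus a set of repeats with
# varied purity.
mapping_fixture <- function() {
  genes <- gene_models(list(
    list(transcriptId = "NM_0001", chrom = "chr1", strand = "+",
         txStart = 10000, txEnd = 16000, cdsStart = 10400, cdsEnd = 15500,
         exonStarts = c(10000, 12000), exonEnds = c(10600, 16000),
         geneSymbol = "GA"),
    list(transcriptId = "NR_0002", chrom = "chr1", strand = "-",
         txStart = 7000, txEnd = 9500, cdsStart = 7000, cdsEnd = 7000,
         exonStarts = 7000, exonEnds = 9500, geneSymbol = "GB")))
  strs <- data.frame(
    chrom = "chr1",
    srStart = c(9200, 8600, 10150, 30000),
    srEnd = c(9240, 8640, 10180, 30030),
    period = c(2L, 3L, 2L, 2L),
    numRepeats = c(20, 13.3, 15, 15),
    consensusSize = c(2L, 3L, 2L, 2L),
    perMatch = c(100L, 89L, 95L, 100L),
    perIndel = 0L, score = c(80, 50, 52, 60),
    baseA = c(50L, 0L, 0L, 50L), baseC = c(0L, 33L, 50L, 0L),
    baseG = c(0L, 66L, 0L, 0L), baseT = c(50L, 0L, 50L, 50L),
    entropy = c(1, 0.9, 1, 1),
    sequence = c("AT", "GGC", "CT", "AT"), stringsAsFactors = FALSE)
  list(genes = genes, strs = strs,
       regions = regulatory_window(genes))
}

test_that("TxPos matches the printed worked examples on both strands", {
  # plus strand: repeat start minus TSS
  expect_equal(tx_pos(list(chrom = "chr1", srStart = 1101897,
                           srEnd = 1101928),
                      list(chrom = "chr1", strand = "+", txStart = 1102483,
                           txEnd = 1102578)), -586)
  # minus strand: TSS (txEnd) minus repeat end
  expect_equal(tx_pos(list(chrom = "chr1", srStart = 28243107,
                           srEnd = 28243146),
                      list(chrom = "chr1", strand = "-",
                           txStart = 28218048, txEnd = 28241236)), -1910)
  expect_equal(tx_pos(list(chrom = "chr1", srStart = 5000, srEnd = 5030),
                      list(chrom = "chr1", strand = "+", txStart = 5000,
                           txEnd = 9000)), 0)
  expect_error(tx_pos(list(chrom = "chr2", srStart = 1, srEnd = 10),
                      list(chrom = "chr1", strand = "+", txStart = 0,
                           txEnd = 100)), "chromosome")
})

test_that("table membership requires full containment in the window", {
  region <- list(chrom = "chr1", windowStart = 1100483,
                 windowEnd = 1103483)
  expect_true(contained_in_regulatory(
    list(chrom = "chr1", srStart = 1101897, srEnd = 1101928), region))
  expect_false(contained_in_regulatory(
    list(chrom = "chr1", srStart = 1100482, srEnd = 1100520), region))
  expect_true(contained_in_regulatory(
    list(chrom = "chr1", srStart = 1100483, srEnd = 1103483), region))
})

test_that("entity overlap needs just one shared base, half-open", {
  iv <- data.frame(start = c(100, 500), end = c(200, 600))
  expect_true(overlaps_entity(list(srStart = 199, srEnd = 260), iv))
  expect_false(overlaps_entity(list(srStart = 200, srEnd = 500), iv))
  expect_true(overlaps_entity(list(srStart = 510, srEnd = 520), iv))
})

test_that("compartment labels combine promoter windows and genic overlap", {
  expect_setequal(classify_compartments(-100, 41),
                  c("upstream", "proximal_promoter", "core_promoter",
                    "regulatory_region"))
  expect_setequal(classify_compartments(-586, 31),
                  c("upstream", "regulatory_region"))
  # a repeat at TxPos +183 inside the first exon, CDS starting later
  g <- gene_models(list(list(
    transcriptId = "NM_X", chrom = "chr1", strand = "+", txStart = 2487804,
    txEnd = 2495188, cdsStart = 2488100, cdsEnd = 2495000,
    exonStarts = c(2487804, 2490000), exonEnds = c(2488200, 2495188),
    geneSymbol = "TX")))
  expect_setequal(
    classify_compartments(183, 25, g, srStart = 2487987, srEnd = 2488012),
    c("regulatory_region", "proximal_promoter", "five_prime_utr", "exon"))
})

test_that("table construction filters, duplicates shared repeats and sorts", {
  fx <- mapping_fixture()
  tab <- build_starrrt(fx$strs, fx$regions)
  counts <- attr(tab, "counts")
  expect_equal(unname(counts["input"]), 4L)
  expect_equal(unname(counts["after_purity"]), 3L)   # the 89% repeat drops
  # the repeat at 9200 sits in both windows: two rows
  expect_equal(sum(tab$srStart == 9200), 2L)
  expect_setequal(tab$hgncSymbol[tab$srStart == 9200], c("GA", "GB"))
  # no 89%-purity rows; distant repeat not contained anywhere
  expect_false(any(tab$perMatch < 90))
  expect_false(30000 %in% tab$srStart)
  # every emitted row is fully contained and within TxPos bounds
  ri <- match(tab$refSeqId, fx$regions$transcriptId)
  expect_true(all(tab$srStart >= fx$regions$windowStart[ri] &
                    tab$srEnd <= fx$regions$windowEnd[ri]))
  expect_true(all(tab$txPos >= -2000 & tab$txPos + tab$srLength <= 1000))
})

test_that("row count and content are invariant to input ordering", {
  fx <- mapping_fixture()
  tab1 <- build_starrrt(fx$strs, fx$regions)
  tab2 <- build_starrrt(fx$strs[c(3, 1, 4, 2), ],
                        fx$regions[rev(seq_len(nrow(fx$regions))), ])
  attr(tab1, "counts") <- attr(tab2, "counts") <- NULL
  expect_equal(tab1, tab2)
})

test_that("genomic position reconstructs from TxPos on both strands", {
  fx <- mapping_fixture()
  tab <- build_starrrt(fx$strs, fx$regions)
  rebuilt <- ifelse(tab$Strand == "+", tab$chromStart + tab$txPos,
                    tab$chromEnd - tab$txPos - tab$srLength)
  expect_equal(rebuilt, tab$srStart)
})

test_that("TxPos survives reverse-complementing the chromosome", {
  fx <- mapping_fixture()
  L <- 40000
  flip_genes <- fx$genes
  flip_genes$strand <- ifelse(fx$genes$strand == "+", "-", "+")
  flip_genes$txStart <- L - fx$genes$txEnd
  flip_genes$txEnd <- L - fx$genes$txStart
  flip_genes$cdsStart <- L - fx$genes$cdsEnd
  flip_genes$cdsEnd <- L - fx$genes$cdsStart
  for (i in seq_len(nrow(flip_genes))) {
    flip_genes$exonStarts[[i]] <- rev(L - fx$genes$exonEnds[[i]])
    flip_genes$exonEnds[[i]] <- rev(L - fx$genes$exonStarts[[i]])
  }
  flip_strs <- fx$strs
  flip_strs$srStart <- L - fx$strs$srEnd
  flip_strs$srEnd <- L - fx$strs$srStart
  tab <- build_starrrt(fx$strs, fx$regions)
  flip_tab <- build_starrrt(flip_strs, regulatory_window(flip_genes))
  expect_setequal(paste(tab$refSeqId, tab$txPos),
                  paste(flip_tab$refSeqId, flip_tab$txPos))
})
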