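write_gene_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("name", "chrom", "strand", "txStart", "txEnd",
                       "cdsStart", "cdsEnd", "exonCount", "exonStarts",
                       "exonEnds", "geneSymbol"), collapse = "\t"), lines),
             path)
  path
}

gene_row <- function(name = "NM_000001", chrom = "chr1", strand = "+",
                     txStart = 1000, txEnd = 5000, cdsStart = 1200,
                     cdsEnd = 4800, exonStarts = c(1000, 3000),
                     exonEnds = c(2000, 5000), geneSymbol = name) {
  gene_models(list(list(transcriptId = name, chrom = chrom, strand = strand,
                        txStart = txStart, txEnd = txEnd,
                        cdsStart = cdsStart, cdsEnd = cdsEnd,
                        exonStarts = exonStarts, exonEnds = exonEnds,
                        geneSymbol = geneSymbol)))
}

test_that("gene tables parse, validate and categorise rows", {
  path <- write_gene_file(c(
    "NM_002946\tchr1\t-\t28218048\t28241236\t28218673\t28240954\t2\t28218048,28240000\t28219000,28241236\tRPA2",
    "NR_029639\tchr1\t+\t1102483\t1102578\t1102483\t1102483\t1\t1102483\t1102578\tMIR200B",
    "NM_BAD\tchr1\t+\t900\t500\t900\t900\t1\t900\t900\tBAD"))
  genes <- suppressMessages(read_gene_table(path))
  expect_equal(nrow(genes), 2L)          # reversed-bounds row rejected
  expect_equal(genes$txStart[genes$transcriptId == "NM_002946"], 28218048)
  expect_equal(genes$category, c("coding", "noncoding"))
  expect_message(read_gene_table(path), "rejected")

  bad <- write_gene_file(
    "NM_X\tchr1\t+\t100\t900\t100\t900\t1\tabc\t900\tX")
  expect_error(read_gene_table(bad), "line 2")
})

test_that("haplotype and unplaced contigs are excluded by name", {
  g <- rbind(gene_row("NM_1", chrom = "chr1"),
             gene_row("NM_2", chrom = "chr6_cox_hap2"),
             gene_row("NM_3", chrom = "chrUn_gl000220"))
  expect_identical(exclude_nonprimary(g)$transcriptId, "NM_1")
})

test_that("canonical selection is deterministic and order-invariant", {
  g <- rbind(
    gene_row("NM_0010", txStart = 1000, txEnd = 11000, geneSymbol = "G1",
             exonStarts = 1000, exonEnds = 11000, cdsStart = 1100,
             cdsEnd = 10000),
    gene_row("NM_0005", txStart = 1000, txEnd = 8000, geneSymbol = "G1",
             exonStarts = 1000, exonEnds = 8000, cdsStart = 1100,
             cdsEnd = 7000),
    gene_row("NM_0002", txStart = 20000, txEnd = 30000, geneSymbol = "G2",
             exonStarts = 20000, exonEnds = 30000, cdsStart = 20100,
             cdsEnd = 29000),
    gene_row("NM_0030", txStart = 20000, txEnd = 30000, geneSymbol = "G2",
             exonStarts = 20000, exonEnds = 30000, cdsStart = 20100,
             cdsEnd = 29000))
  sel <- select_canonical(g)
  expect_identical(sel$transcriptId, c("NM_0010", "NM_0002"))  # span, then id
  # permutation invariance
  perm <- g[c(3, 1, 4, 2), ]
  expect_identical(select_canonical(perm), sel)
  # explicit canonical list overrides the span rule
  sel2 <- select_canonical(g, canonical_ids = "NM_0005")
  expect_true("NM_0005" %in% sel2$transcriptId)
  expect_warning(select_canonical(g, canonical_ids = "NM_9999"), "absent")
})

test_that("regulatory windows are strand-aware, clamped and 3 kb wide", {
  minus <- gene_row("NM_002946", strand = "-", txStart = 28218048,
                    txEnd = 28241236, cdsStart = 28218673,
                    cdsEnd = 28240954, exonStarts = 28218048,
                    exonEnds = 28241236)
  w <- regulatory_window(minus)
  expect_equal(w$tss, 28241236)
  expect_equal(w$windowStart, 28240236)
  expect_equal(w$windowEnd, 28243236)

  plus <- gene_row(txStart = 10000, txEnd = 15000, cdsStart = 10100,
                   cdsEnd = 14000, exonStarts = 10000, exonEnds = 15000)
  w <- regulatory_window(plus)
  expect_equal(c(w$windowStart, w$windowEnd), c(8000, 11000))
  expect_equal(w$windowEnd - w$windowStart, 3000)

  edge <- gene_row(txStart = 500, txEnd = 4000, cdsStart = 600,
                   cdsEnd = 3500, exonStarts = 500, exonEnds = 4000)
  w <- regulatory_window(edge, chrom_lengths = c(chr1 = 100000))
  expect_equal(c(w$windowStart, w$windowEnd), c(0, 1500))
})

test_that("compartments partition the transcript and respect orientation", {
  g <- gene_row(txStart = 0, txEnd = 300, cdsStart = 50, cdsEnd = 280,
                exonStarts = c(0, 200), exonEnds = c(100, 300))
  comp <- gene_compartments(g)
  expect_equal(comp$introns, data.frame(start = 100, end = 200))
  expect_equal(comp$fiveUTR, data.frame(start = 0, end = 50))

  single <- gene_row(exonStarts = 1000, exonEnds = 5000)
  expect_equal(nrow(gene_compartments(single)$introns), 0L)

  minus <- gene_row(strand = "-", txStart = 0, txEnd = 300, cdsStart = 50,
                    cdsEnd = 300, exonStarts = c(0, 200),
                    exonEnds = c(100, 300))
  expect_equal(nrow(gene_compartments(minus)$fiveUTR), 0L)  # CDS at the TSS

  # width identity over simulated models
  sim <- sim_fixture()
  for (i in sample(nrow(sim$genes), 20)) {
    g <- sim$genes[i, , drop = FALSE]
    comp <- gene_compartments(g)
    expect_equal(sum(comp$exons$end - comp$exons$start) +
                   sum(comp$introns$end - comp$introns$start),
                 g$txEnd - g$txStart)
  }
})

test_that("CpG overlap uses half-open, >= 1 bp intersection", {
  g <- gene_row(txStart = 10000, txEnd = 15000, cdsStart = 10100,
                cdsEnd = 14000, exonStarts = 10000, exonEnds = 15000)
  regions <- regulatory_window(g)   # window [8000, 11000)
  isl <- data.frame(chrom = "chr1", start = 7990, end = 8005)
  expect_true(flag_cpg_overlap(regions, isl)$cpgOverlap)
  isl <- data.frame(chrom = "chr1", start = 7000, end = 8000)
  expect_false(flag_cpg_overlap(regions, isl)$cpgOverlap)
  expect_message(out <- flag_cpg_overlap(regions, NULL), "no CpG")
  expect_false(out$cpgOverlap)
})
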