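test_that("the regulatory-region gene set deduplicates loci", {
  rows <- data.frame(hgncSymbol = c("SPSB1", "SPSB1", "MIR200B"),
                     refSeqId = c("NM_025106", "NM_025106", "NR_029639"))
  s <- starrrt_gene_set(rows)
  expect_setequal(s$genes, c("SPSB1", "MIR200B"))
  expect_lte(length(s$genes), nrow(rows))
  empty <- starrrt_gene_set(rows[0, ])
  expect_equal(length(empty$genes), 0L)
})

test_that("the exonic set ignores purity and requires exon overlap", {
  genes <- gene_models(list(
    list(transcriptId = "NM_1", chrom = "chr1", strand = "+",
         txStart = 1000, txEnd = 9000, cdsStart = 1500, cdsEnd = 8500,
         exonStarts = c(1000, 5000), exonEnds = c(2000, 9000),
         geneSymbol = "EX1"),
    list(transcriptId = "NM_2", chrom = "chr1", strand = "+",
         txStart = 20000, txEnd = 30000, cdsStart = 20500, cdsEnd = 29000,
         exonStarts = c(20000, 25000), exonEnds = c(21000, 30000),
         geneSymbol = "EX2")))
  strs <- data.frame(chrom = "chr1",
                     srStart = c(1500, 22000, 20990),
                     srEnd = c(1530, 22030, 21020),
                     perMatch = c(85L, 100L, 100L))
  s <- exonic_gene_set(strs, genes)
  # 85%-purity exonic repeat still qualifies EX1; boundary-straddling
  # repeat qualifies EX2; the intronic repeat at 22000 does not by itself
  expect_setequal(s$genes, c("EX1", "EX2"))
  intronic_only <- exonic_gene_set(strs[2, ], genes)
  expect_equal(length(intronic_only$genes), 0L)
})

test_that("intronic density is kb of intron per high-purity repeat", {
  genes <- gene_models(list(list(
    transcriptId = "NM_1", chrom = "chr1", strand = "+",
    txStart = 0, txEnd = 15640, cdsStart = 100, cdsEnd = 15500,
    exonStarts = c(0, 15140), exonEnds = c(500, 15640),
    geneSymbol = "D1")))           # one 14,640 bp intron
  strs <- data.frame(chrom = "chr1",
                     srStart = c(1000, 9000, 12000),
                     srEnd = c(1030, 9030, 12030),
                     perMatch = c(100L, 95L, 85L))
  d <- intron_kb_per_str(genes, strs)
  expect_equal(d$n_strs, 2L)                 # the 85% repeat is not counted
  expect_equal(d$kb_per_str, 7.32)
  d5 <- intron_kb_per_str(
    gene_models(list(list(transcriptId = "NM_2", chrom = "chr1",
                          strand = "+", txStart = 0, txEnd = 5200,
                          cdsStart = 10, cdsEnd = 5150,
                          exonStarts = c(0, 5100), exonEnds = c(100, 5200),
                          geneSymbol = "D2"))),
    data.frame(chrom = "chr1", srStart = seq(200, 4200, by = 1000),
               srEnd = seq(230, 4230, by = 1000), perMatch = 100L))
  expect_equal(d5$kb_per_str, 1)
})

test_that("the highest-density quartile interpolates and keeps ties", {
  d <- data.frame(geneSymbol = paste0("G", 1:8), intron_kb = 1:8,
                  n_strs = 1L, kb_per_str = as.numeric(1:8))
  sel <- high_density_quartile(d)
  expect_setequal(sel$genes, c("G1", "G2"))      # 25th percentile = 2.75
  tied <- d
  tied$kb_per_str <- rep(2, 8)
  expect_equal(length(high_density_quartile(tied)$genes), 8L)
  expect_warning(small <- high_density_quartile(d[1:3, ]), "fewer than 4")
  expect_equal(length(small$genes), 3L)
  # selection fraction always within [25%, 25% + tie share]
  set.seed(41)
  for (i in 1:20) {
    n <- sample(8:60, 1)
    vals <- sample(1:10, n, replace = TRUE)
    dd <- data.frame(geneSymbol = paste0("g", 1:n), intron_kb = 1,
                     n_strs = 1L, kb_per_str = as.numeric(vals))
    sel <- high_density_quartile(dd)
    frac <- length(sel$genes) / n
    thr <- sel$provenance$threshold
    ties <- sum(vals == max(vals[vals <= thr])) / n
    expect_gte(frac, 0.25 - 1e-9)
    expect_lte(frac, 0.25 + ties + 1e-9)
  }
})

test_that("random samples are reproducible and uniform", {
  pool <- gene_set("pool", paste0("g", 1:100))
  s1 <- random_gene_samples(pool, 10, k = 5, seed = 7)
  s2 <- random_gene_samples(pool, 10, k = 5, seed = 7)
  expect_identical(lapply(s1, `[[`, "genes"), lapply(s2, `[[`, "genes"))
  expect_false(identical(s1[[1]]$genes, s1[[2]]$genes))
  full <- random_gene_samples(pool, 100, k = 2, seed = 1)
  expect_setequal(full[[1]]$genes, pool$genes)
  expect_error(random_gene_samples(pool, 101, seed = 1), "exceeds")
  # inclusion frequency over many draws: exactly 0.10 on average, each
  # gene within 4 standard errors (fixed seed)
  draws <- random_gene_samples(pool, 10, k = 1000, seed = 99)
  freq <- table(factor(unlist(lapply(draws, `[[`, "genes")),
                       levels = pool$genes)) / 1000
  expect_equal(mean(freq), 0.1)
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(freq - 0.1) <= 4 * se))
})

test_that("hypergeometric p-values equal exhaustive enumeration (N <= 12)", {
  cases <- list(c(N = 12, K = 5, n = 6), c(N = 10, K = 3, n = 4),
                c(N = 9, K = 6, n = 3), c(N = 12, K = 2, n = 7))
  for (cs in cases) {
    bg <- paste0("g", seq_len(cs["N"]))
    term_map <- data.frame(term = "T1", gene = bg[seq_len(cs["K"])])
    for (rep in 1:3) {
      set.seed(rep * 17)
      sel <- sample(bg, cs["n"])
      res <- hypergeometric_enrichment(sel, bg, term_map)
      k <- sum(sel %in% term_map$gene)
      expect_equal(res$p,
                   oracle_hyper_tail(cs["N"], cs["K"], cs["n"], k),
                   tolerance = 1e-12)
      expect_equal(res$fold, (k / cs[["n"]]) / (cs[["K"]] / cs[["N"]]))
    }
  }
  # degenerate cases: whole-background term, and an absent term
  bg <- paste0("g", 1:20)
  res <- hypergeometric_enrichment(bg[1:5], bg,
                                   data.frame(term = "ALL", gene = bg))
  expect_equal(res$fold, 1)
  expect_equal(res$p, 1)
  res0 <- hypergeometric_enrichment(
    bg[1:5], bg, data.frame(term = "NONE", gene = bg[6:10]))
  expect_equal(res0$fold, 0)
  expect_equal(res0$p, 1)
  expect_error(hypergeometric_enrichment(c("zz"), bg,
                                         data.frame(term = "T", gene = bg)),
               "subset")
})

test_that("the step-up FDR matches the reference implementation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(57)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_false(is.unsorted(q[order(p)]))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("majority consensus requires agreement across samples", {
  mk <- function(fdrs) data.frame(term = paste0("T", seq_along(fdrs)),
                                  fdr = fdrs)
  results <- c(replicate(6, mk(c(0.01, 0.2)), simplify = FALSE),
               replicate(4, mk(c(0.2, 0.01)), simplify = FALSE))
  expect_identical(majority_consensus(results), "T1")   # 6/10 vs 4/10
  results5 <- c(replicate(5, mk(c(0.01, 0.2)), simplify = FALSE),
                replicate(5, mk(c(0.2, 0.2)), simplify = FALSE))
  expect_identical(majority_consensus(results5), character(0))
  expect_identical(
    majority_consensus(list(mk(c(0.01, 0.2))), min_agree = 1), "T1")
})
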