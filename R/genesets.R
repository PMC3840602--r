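# Comparison gene sets (regulatory-region, exonic, high-density intron,
# random intron samples) and over-representation statistics.

#' Construct a gene set
#'
#' @param name Label.
#' @param genes Character vector of gene identifiers (deduplicated).
#' @param provenance Named list recording how the set was built (filters,
#'   seed), sufficient to reproduce it.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes, provenance = list()) {
  structure(list(name = name, genes = unique(as.character(genes)),
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$name, length(x$genes)))
  invisible(x)
}

.set_genes <- function(x) if (inherits(x, "gene_set")) x$genes else
  unique(as.character(x))

#' Genes with at least one repeat in their regulatory region
#'
#' Unique gene loci having >= 1 table row (a locus with several rows, like
#' a gene carrying two qualifying repeats, appears once).
#'
#' @param rows Table rows from [build_starrrt()].
#' @return A [gene_set()].
#' @export
starrrt_gene_set <- function(rows) {
  g <- ifelse(nzchar(rows$hgncSymbol), rows$hgncSymbol, rows$refSeqId)
  gene_set("regulatory_region_str", g,
           provenance = list(rule = "≥1 table row per locus"))
}

#' Genes with at least one exonic repeat, regardless of purity
#'
#' Uses the any-overlap rule against each gene's exons and applies NO
#' purity filter (the exonic comparison set deliberately keeps impure
#' repeats).
#'
#' @param all_strs Full repeat table (unfiltered).
#' @param genes Gene-model data.frame.
#' @return A [gene_set()].
#' @export
exonic_gene_set <- function(all_strs, genes) {
  hit <- .genes_overlapping(all_strs, genes, "exons")
  gene_set("exonic_str", genes$geneSymbol[hit],
           provenance = list(rule = "any exon overlap, no purity filter"))
}

# Which genes have >= 1 repeat overlapping the named compartment.
.genes_overlapping <- function(strs, genes, compartment) {
  if (nrow(strs) == 0L || nrow(genes) == 0L) return(logical(nrow(genes)))
  iv <- lapply(seq_len(nrow(genes)),
               function(i) gene_compartments(genes[i, , drop = FALSE])[[compartment]])
  n_per <- vapply(iv, nrow, integer(1))
  gi <- rep(seq_len(nrow(genes)), n_per)
  if (length(gi) == 0L) return(logical(nrow(genes)))
  iv <- do.call(rbind, iv)
  comp_gr <- GenomicRanges::GRanges(genes$chrom[gi],
                                    IRanges::IRanges(iv$start + 1L, iv$end))
  str_gr <- GenomicRanges::GRanges(strs$chrom,
                                   IRanges::IRanges(strs$srStart + 1L,
                                                    strs$srEnd))
  hits <- GenomicRanges::findOverlaps(comp_gr, str_gr)
  seq_len(nrow(genes)) %in% gi[S4Vectors::queryHits(hits)]
}

#' Intronic repeat density per gene, in kb of intron per repeat
#'
#' For each gene with at least one qualifying intronic repeat (purity >=
#' `min_purity`, any overlap with an intron), total intron width in kb
#' divided by the number of qualifying repeats. Smaller values mean denser.
#' Genes without qualifying repeats are absent from the result.
#'
#' @param genes Gene-model data.frame.
#' @param strs Repeat table.
#' @param min_purity Purity threshold for a repeat to count (default 90).
#' @return data.frame with `geneSymbol`, `intron_kb`, `n_strs`,
#'   `kb_per_str`.
#' @export
intron_kb_per_str <- function(genes, strs, min_purity = 90) {
  strs <- strs[strs$perMatch >= min_purity, , drop = FALSE]
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    introns <- gene_compartments(g)$introns
    if (nrow(introns) == 0L) return(NULL)
    sub <- strs[strs$chrom == g$chrom, , drop = FALSE]
    k <- sum(vapply(seq_len(nrow(sub)), function(j) {
      overlaps_entity(sub[j, , drop = FALSE], introns)
    }, logical(1)))
    if (k == 0L) return(NULL)
    kb <- sum(introns$end - introns$start) / 1000
    data.frame(geneSymbol = g$geneSymbol, intron_kb = kb, n_strs = k,
               kb_per_str = kb / k, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(geneSymbol = character(0), intron_kb = numeric(0),
                      n_strs = integer(0), kb_per_str = numeric(0)))
  }
  do.call(rbind, out)
}

#' Highest-quartile intronic-density gene set
#'
#' Selects genes whose kb-per-repeat value is at or below the 25th
#' percentile of the density table (smallest kb-per-repeat = highest
#' density), computed by linear interpolation; boundary ties are included.
#' With fewer than 4 genes, all genes are returned with a warning.
#'
#' @param gene_densities Output of [intron_kb_per_str()].
#' @param quartile Quantile cut, default 0.25.
#' @return A [gene_set()] carrying the threshold in its provenance.
#' @export
high_density_quartile <- function(gene_densities, quartile = 0.25) {
  if (nrow(gene_densities) < 4L) {
    warning("fewer than 4 genes in the density table; returning all genes")
    return(gene_set("high_density_intron", gene_densities$geneSymbol,
                    provenance = list(threshold = NA_real_)))
  }
  thr <- unname(stats::quantile(gene_densities$kb_per_str, quartile,
                                type = 7))
  sel <- gene_densities$kb_per_str <= thr
  gene_set("high_density_intron", gene_densities$geneSymbol[sel],
           provenance = list(threshold = thr, quartile = quartile))
}

#' Random gene samples of fixed size from a pool
#'
#' `k` sets sampled uniformly without replacement (within each set,
#' independently across sets), reproducible from `seed`.
#'
#' @param pool A [gene_set()] or character vector to sample from.
#' @param size Sample size; must not exceed the pool.
#' @param k Number of samples (default 10).
#' @param seed RNG seed.
#' @return List of [gene_set()] objects.
#' @export
random_gene_samples <- function(pool, size, k = 10, seed = 1) {
  genes <- .set_genes(pool)
  if (size > length(genes)) stop("size exceeds the pool")
  with_seed(seed, lapply(seq_len(k), function(i) {
    gene_set(sprintf("random_sample_%02d", i), sample(genes, size),
             provenance = list(seed = seed, index = i, size = size))
  }))
}

#' Hypergeometric over-representation of terms in a gene set
#'
#' For each term with at least one background gene: `k` set genes carrying
#' the term, `K` background genes carrying it, fold enrichment
#' `(k/n)/(K/N)` and the upper-tail hypergeometric probability
#' `P(X >= k)`, with Benjamini-Hochberg adjusted values over the term
#' collection.
#'
#' @param set Gene set of interest; must be a subset of `background`.
#' @param background Background gene universe.
#' @param term_map data.frame with columns `term` and `gene`.
#' @return data.frame with `term`, `k`, `K`, `n`, `N`, `fold`, `p`, `fdr`.
#' @export
hypergeometric_enrichment <- function(set, background, term_map) {
  sg <- .set_genes(set)
  bg <- .set_genes(background)
  if (length(setdiff(sg, bg)) > 0L) {
    stop("set must be a subset of the background")
  }
  term_map <- term_map[term_map$gene %in% bg, , drop = FALSE]
  by_term <- split(unique(term_map[c("term", "gene")])$gene,
                   unique(term_map[c("term", "gene")])$term)
  n <- length(sg)
  N <- length(bg)
  res <- lapply(names(by_term), function(tm) {
    K <- length(by_term[[tm]])
    k <- sum(sg %in% by_term[[tm]])
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               fold = (k / n) / (K / N),
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  if (length(res) == 0L) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), fold = numeric(0),
                      p = numeric(0), fdr = numeric(0)))
  }
  res <- do.call(rbind, res)
  res$fdr <- bh_fdr(res$p)
  res
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorted ascending, `q_i = min_{j >= i}(p_j * m / j)`, capped at 1 and
#' returned in input order. Written out explicitly so it can be
#' cross-checked against `stats::p.adjust`.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  q <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Majority-consensus term reporting over repeated analyses
#'
#' Terms significant (`fdr < alpha`) in at least `min_agree` of the `k`
#' result lists; with `k = 1` and `min_agree = 1` this is a plain
#' significance filter.
#'
#' @param results List of [hypergeometric_enrichment()] results over a
#'   shared term universe.
#' @param alpha Significance level (default 0.05).
#' @param min_agree Minimum number of agreeing lists (default 6).
#' @return Sorted character vector of reported terms.
#' @export
majority_consensus <- function(results, alpha = 0.05, min_agree = 6) {
  sig <- unlist(lapply(results, function(r) unique(r$term[r$fdr < alpha])))
  counts <- table(sig)
  sort(names(counts)[counts >= min_agree])
}
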