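# Synthetic genomes with planted repeats and known truth, so every
# pipeline stage is testable without external downloads. The generator is
# substitution-only (matching the detector's model): planted truth always
# has perIndel = 0.

#' Describe one group of repeats to plant
#'
#' @param count Number of repeats in the group.
#' @param motifs Character vector of motifs to sample uniformly, or `NULL`
#'   to draw random primitive motifs from `periods`.
#' @param periods List `list(values=, weights=)` of repeat-unit lengths to
#'   sample when `motifs` is `NULL`.
#' @param copies Integer range `c(min, max)` of repeat-unit copies
#'   (ignored when `tract_len` is given).
#' @param tract_len Optional target tract-length range `c(min, max)` in bp;
#'   copies are derived per motif so groups with mixed periods plant
#'   comparable tract lengths.
#' @param purity Vector of purity targets (percent, each in \[70, 100\])
#'   sampled uniformly per repeat.
#' @param placement `"window"` (TSS-relative placement in a gene's
#'   regulatory window) or `"genome"` (uniform over the genome).
#' @param txpos For window placement: either `c(min, max)` for a uniform
#'   TxPos draw or `list(mean=, sd=, min=, max=)` for a truncated normal.
#' @param cpg_only Restrict window placement to CpG-island genes.
#' @param name Group label carried into the truth table.
#' @return A `plant_group` list.
#' @export
plant_spec_group <- function(count, motifs = NULL, periods = NULL,
                             copies = c(13, 25), tract_len = NULL,
                             purity = 100,
                             placement = c("window", "genome"),
                             txpos = c(-1950, -100), cpg_only = FALSE,
                             name = "group") {
  placement <- match.arg(placement)
  if (is.null(motifs) && is.null(periods)) {
    stop("supply either motifs or periods")
  }
  if (any(purity < 70 | purity > 100)) {
    stop("purity targets must lie in [70, 100]")
  }
  if (!is.null(periods) && abs(sum(periods$weights) - 1) > 1e-6) {
    stop("period weights must sum to 1")
  }
  list(count = count, motifs = motifs, periods = periods, copies = copies,
       tract_len = tract_len, purity = purity, placement = placement,
       txpos = txpos, cpg_only = cpg_only, name = name)
}

#' Default planting specification
#'
#' Emulates the structure of repeats around human TSSs: AT-rich
#' dinucleotides spread over the upstream region, GC-rich trinucleotides
#' concentrated near the TSS of CpG-island genes, a genome-wide background
#' of mixed periods (dinucleotide-dominated), and a small group of
#' sub-25 bp tracts that fall below the reporting threshold so the score
#' filter is observable.
#'
#' @return List of [plant_spec_group()] objects.
#' @export
default_plant_spec <- function() {
  list(
    plant_spec_group(120, motifs = c("AT", "TA", "AT", "TA", "TG", "CA"),
                     copies = c(13, 25), purity = 100,
                     placement = "window", txpos = c(-1950, -150),
                     name = "upstream_dinuc"),
    plant_spec_group(30, motifs = c("AT", "TA"), copies = c(23, 30),
                     purity = 96, placement = "window",
                     txpos = c(-1950, -150), name = "upstream_dinuc_impure"),
    plant_spec_group(15, motifs = c("AT", "CA"), copies = c(25, 35),
                     purity = 85, placement = "window",
                     txpos = c(-1800, -200), name = "lowpurity_dinuc"),
    plant_spec_group(80, motifs = c("GGC", "GCC", "CGG", "CCG"),
                     copies = c(9, 14), purity = 100,
                     placement = "window",
                     txpos = list(mean = 0, sd = 150, min = -350, max = 300),
                     cpg_only = TRUE, name = "tss_trinuc"),
    plant_spec_group(20, motifs = c("GGC", "GCC"), copies = c(15, 20),
                     purity = 95, placement = "window",
                     txpos = list(mean = 0, sd = 150, min = -350, max = 280),
                     cpg_only = TRUE, name = "tss_trinuc_impure"),
    plant_spec_group(250,
                     periods = list(values = 1:9,
                                    weights = c(0.24, 0.29, 0.12, 0.08,
                                                0.07, 0.06, 0.05, 0.05,
                                                0.04)),
                     tract_len = c(27, 63), purity = c(100, 100, 97),
                     placement = "genome", name = "genome_bg"),
    plant_spec_group(20, motifs = c("AC", "AG"), copies = c(10, 12),
                     purity = 100, placement = "genome",
                     name = "short_subthreshold")
  )
}

#' Simulation configuration
#'
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Number of gene loci (one transcript each).
#' @param strand_prob Probability of the plus strand.
#' @param background_gc Background GC fraction.
#' @param plant_spec List of [plant_spec_group()] (see
#'   [default_plant_spec()]).
#' @param cpg_fraction Fraction of genes whose window receives a CpG
#'   island.
#' @param term_spec Optional list `list(n_terms=, term_size=, fold=)`:
#'   assigns `n_terms` random gene sets as annotation terms and biases the
#'   window-placed repeat groups toward genes of the first term with
#'   sampling weight `fold`.
#' @param plant_gap Minimum distance (bp) between planted tracts and from
#'   exon boundaries.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_length = 8e5,
                       n_genes = 100, strand_prob = 0.5,
                       background_gc = 0.4,
                       plant_spec = default_plant_spec(),
                       cpg_fraction = 0.5, term_spec = NULL,
                       plant_gap = 100) {
  stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 1,
            strand_prob >= 0, strand_prob <= 1,
            background_gc > 0, background_gc < 1,
            cpg_fraction >= 0, cpg_fraction <= 1)
  structure(list(seed = seed, n_chroms = n_chroms,
                 chrom_length = chrom_length, n_genes = n_genes,
                 strand_prob = strand_prob, background_gc = background_gc,
                 plant_spec = plant_spec, cpg_fraction = cpg_fraction,
                 term_spec = term_spec, plant_gap = plant_gap),
            class = "sim_config")
}

# -- planting -----------------------------------------------------------

#' Write a repeat tract into a sequence at a target purity
#'
#' Writes `motif` repeated `copies` times at 1-based position `pos`, then
#' applies substitutions at distinct interior tract positions (kept clear
#' of both ends so trimming never shortens the optimal span) until the
#' realized purity is within +/-2 percentage points of `target_purity`.
#' Substitutions that distort the majority-vote consensus are resampled.
#' Uses the caller's RNG state.
#'
#' @param chars Sequence as a character vector of bases.
#' @param pos 1-based start position; the tract must fit.
#' @param motif Repeat unit over A/C/G/T.
#' @param copies Number of copies (integer).
#' @param target_purity Target percent match in \[70, 100\].
#' @return List with the mutated `chars`, the realized `purity`, `srStart`
#'   (0-based), `srEnd` and `n_subs`.
#' @export
plant_repeat <- function(chars, pos, motif, copies, target_purity = 100) {
  if (target_purity < 70 || target_purity > 100) {
    stop("purity target unreachable: must lie in [70, 100]")
  }
  p <- nchar(motif)
  L <- p * copies
  if (pos < 1 || pos + L - 1 > length(chars)) stop("tract does not fit")
  mo <- .dna_chars(motif)
  tract <- rep(mo, length.out = L)
  n_subs <- 0L
  if (target_purity < 100) {
    allowed <- seq.int(p + 3L, L - p - 2L)
    if (length(allowed) < 1L) {
      stop("purity target unreachable: tract too short for interior substitutions")
    }
    want <- max(1L, as.integer(round(L * (100 - target_purity) / 100)))
    done <- FALSE
    for (try in 1:80) {
      if (want < 1L || want > length(allowed)) break
      at <- .spaced_positions(L, p, want)
      cand <- tract
      for (i in at) {
        cand[i] <- sample(setdiff(VALID_BASES, tract[i]), 1L)
      }
      if (paste(.consensus_vote(cand, p), collapse = "") != motif) next
      realized <- compute_purity(paste(cand, collapse = ""), motif)
      if (abs(realized - target_purity) <= 2) {
        tract <- cand
        n_subs <- want
        done <- TRUE
        break
      }
      if (realized > target_purity + 2) want <- want + 1L
      if (realized < target_purity - 2) want <- want - 1L
    }
    if (!done) stop("purity target unreachable within +/-2 points")
  }
  chars[pos:(pos + L - 1L)] <- tract
  list(chars = chars,
       purity = compute_purity(paste(tract, collapse = ""), motif),
       srStart = pos - 1L, srEnd = pos - 1L + L, n_subs = n_subs)
}

# Substitution positions kept clear of the tract ends and mutually spaced
# so that a high-purity planted tract stays score-optimal at exactly its
# planted span (every prefix/suffix of the tract keeps a non-negative
# score contribution). Falls back to plain interior sampling when the
# purity target needs more substitutions than the spacing allows.
.sub_margin <- function(p) p + max(12L, 2L * p) + 1L

.spacing_capacity <- function(L, p) {
  margin <- .sub_margin(p)
  sep <- p + 10L
  width <- L - 2L * margin + 1L
  if (width < 1L) 0L else (width - 1L) %/% sep + 1L
}

.spaced_positions <- function(L, p, s) {
  margin <- .sub_margin(p)
  sep <- p + 10L
  width <- L - 2L * margin + 1L
  reduced <- width - (s - 1L) * sep
  if (reduced >= s) {
    base <- sort(sample.int(reduced, s))
    return(margin + base - 1L + (seq_len(s) - 1L) * sep)
  }
  allowed <- seq.int(p + 3L, L - p - 2L)
  if (length(allowed) < s) {
    stop("purity target unreachable: tract too short for interior substitutions")
  }
  sample(allowed, s)
}

# Ensure the score-optimal span at period p ends exactly at the planted
# tract: walk outward and break any background autocorrelation run that
# would make an extension profitable, then keep forcing the cumulative
# extension score well below zero so later background cannot recover.
.break_flanks <- function(chars, s1, e1, p, w = 2, pen = 7, reach = 80) {
  n <- length(chars)
  cum <- 0
  step <- 0L
  for (i in seq.int(e1 + 1L, length.out = min(reach, n - e1))) {
    step <- step + 1L
    if (chars[i] == chars[i - p]) cum <- cum + w else cum <- cum - pen
    lim <- if (step <= 12L) 0 else -10
    if (cum > lim) {
      chars[i] <- sample(setdiff(VALID_BASES, chars[i - p]), 1L)
      cum <- cum - w - pen
    }
  }
  cum <- 0
  step <- 0L
  for (k in seq_len(min(reach, s1 - 1L))) {
    step <- step + 1L
    i <- s1 - k
    if (chars[i] == chars[i + p]) cum <- cum + w else cum <- cum - pen
    lim <- if (step <= 12L) 0 else -10
    if (cum > lim) {
      chars[i] <- sample(setdiff(VALID_BASES, chars[i + p]), 1L)
      cum <- cum - w - pen
    }
  }
  chars
}

# uniform integer in [a, b] robust to a == b (sample() would misread it)
.rint <- function(a, b) {
  if (a >= b) return(as.integer(a))
  as.integer(a + sample.int(b - a + 1L, 1L) - 1L)
}

.draw_txpos <- function(spec, n = 1L) {
  if (is.list(spec)) {
    x <- round(stats::rnorm(n, spec$mean, spec$sd))
    pmin(pmax(x, spec$min), spec$max)
  } else {
    vapply(seq_len(n), function(i) .rint(spec[1L], spec[2L]), integer(1))
  }
}

.random_primitive_motif <- function(p) {
  repeat {
    m <- paste(sample(VALID_BASES, p, replace = TRUE), collapse = "")
    if (nchar(primitive_motif(m)) == p) return(m)
  }
}

# Does [s0, e0) keep at least `gap` bp clearance from previously planted
# tracts on the same chromosome?
.clear_of <- function(planted, s0, e0, gap) {
  if (nrow(planted) == 0L) return(TRUE)
  all(s0 - gap >= planted$end | e0 + gap <= planted$start)
}

# -- genome simulation --------------------------------------------------

#' Simulate a genome with genes, CpG islands and planted repeats
#'
#' Generates i.i.d. background sequence at the configured GC fraction,
#' places non-overlapping genes (2-5 exons, 90% coding) on both strands,
#' writes CpG islands over a configurable fraction of TSS windows, and
#' plants repeats per the plant specification: TSS-relative placement for
#' window groups (CpG-restricted where requested, term-biased when a term
#' specification is present) and uniform placement for genome groups.
#' Planted tracts keep `plant_gap` bp clearance from each other and from
#' exon boundaries, and their flanks are adjusted so the score-optimal
#' span is exactly the planted tract. Fully reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `sequences` (named character vector), `genes`,
#'   `regions` metadata inputs (`cpg` islands BED-like), `truth` (one row
#'   per planted repeat, leading columns in repeat-table layout),
#'   `term_map` (or `NULL`) and the `config`.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config")
  with_seed(cfg$seed, .simulate_genome_impl(cfg))
}

.simulate_genome_impl <- function(cfg) {
  gc <- cfg$background_gc
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- lapply(chrom_names, function(ch) {
    sample(VALID_BASES, cfg$chrom_length, replace = TRUE, prob = probs)
  })
  names(seqs) <- chrom_names

  # gene placement in fixed slots so windows never cross chromosome ends
  slot <- 14000L
  margin <- 2600L
  per_chrom <- (cfg$chrom_length - 2L * margin) %/% slot
  total <- per_chrom * cfg$n_chroms
  if (cfg$n_genes > total) {
    stop(sprintf("infeasible placement: %d genes exceed %d available slots",
                 cfg$n_genes, total))
  }
  slots <- sort(sample(total, cfg$n_genes))
  rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    ci <- (slots[i] - 1L) %/% per_chrom + 1L
    si <- (slots[i] - 1L) %% per_chrom
    base <- margin + si * slot
    glen <- sample(3000:8000, 1L)
    txStart <- base + sample.int(slot - glen - 2L * margin + 1L, 1L) +
      margin - 1L
    txEnd <- txStart + glen
    strand <- if (stats::runif(1) < cfg$strand_prob) "+" else "-"
    n_ex <- sample(2:5, 1L)
    parts <- 2L * n_ex - 1L
    u <- stats::runif(parts, 0.5, 1.5)
    widths <- 100L + floor((glen - 100L * parts) * u / sum(u))
    widths[parts] <- glen - sum(widths[-parts])
    bounds <- txStart + cumsum(c(0L, widths))
    es <- bounds[seq(1L, parts, by = 2L)]
    ee <- bounds[seq(2L, parts + 1L, by = 2L)]
    coding <- stats::runif(1) < 0.9
    if (coding) {
      cdsStart <- txStart + sample(50:600, 1L)
      cdsEnd <- txEnd - sample(50:400, 1L)
    } else {
      cdsStart <- cdsEnd <- txStart
    }
    rows[[i]] <- list(
      transcriptId = sprintf("%s_%06d", if (coding) "NM" else "NR", i),
      chrom = chrom_names[ci], strand = strand,
      txStart = txStart, txEnd = txEnd,
      cdsStart = cdsStart, cdsEnd = cdsEnd,
      exonStarts = es, exonEnds = ee,
      geneSymbol = sprintf("GENE%04d", i))
  }
  genes <- gene_models(rows)

  # CpG islands over a fraction of TSS windows
  n_cpg <- floor(cfg$cpg_fraction * nrow(genes))
  cpg_idx <- sort(sample(nrow(genes), n_cpg))
  tss <- ifelse(genes$strand == "+", genes$txStart, genes$txEnd)
  cpg <- data.frame(chrom = genes$chrom[cpg_idx],
                    start = pmax(tss[cpg_idx] - 300, 0),
                    end = tss[cpg_idx] + 300,
                    stringsAsFactors = FALSE)

  # optional term universe with one enriched term
  term_map <- NULL
  gene_weights <- rep(1, nrow(genes))
  if (!is.null(cfg$term_spec)) {
    ts <- cfg$term_spec
    term_map <- do.call(rbind, lapply(seq_len(ts$n_terms), function(t) {
      data.frame(term = sprintf("TERM%02d", t),
                 gene = sample(genes$geneSymbol, ts$term_size),
                 stringsAsFactors = FALSE)
    }))
    enriched <- term_map$gene[term_map$term == "TERM01"]
    gene_weights[genes$geneSymbol %in% enriched] <- ts$fold
  }

  planted <- lapply(chrom_names, function(ch) {
    data.frame(start = numeric(0), end = numeric(0))
  })
  names(planted) <- chrom_names
  gap <- cfg$plant_gap
  truth <- list()

  for (grp in cfg$plant_spec) {
    pool <- seq_len(nrow(genes))
    if (isTRUE(grp$cpg_only)) pool <- cpg_idx
    for (r in seq_len(grp$count)) {
      motif <- if (!is.null(grp$motifs)) sample(grp$motifs, 1L) else
        .random_primitive_motif(sample(grp$periods$values, 1L,
                                       prob = grp$periods$weights))
      p <- nchar(motif)
      copies <- if (!is.null(grp$tract_len)) {
        max(2L, as.integer(ceiling(.rint(grp$tract_len[1L],
                                         grp$tract_len[2L]) / p)))
      } else {
        .rint(grp$copies[1L], grp$copies[2L])
      }
      L <- p * copies
      target <- if (length(grp$purity) == 1L) grp$purity else
        sample(grp$purity, 1L)
      # impure tracts meant to be detectable are lengthened until the
      # substitution load still clears the reporting score with margin
      if (target >= 90 && target < 100) {
        repeat {
          projected <- max(1L, round(L * (100 - target) / 100))
          if (2 * L - 18 * (projected + 2) >= 52 &&
              .spacing_capacity(L, p) >= projected + 1L) break
          copies <- copies + 1L
          L <- p * copies
        }
      }
      ok <- FALSE
      for (try in 1:200) {
        if (grp$placement == "window") {
          gi <- pool[sample.int(length(pool), 1L,
                                prob = gene_weights[pool])]
          g <- genes[gi, , drop = FALSE]
          txp <- .draw_txpos(grp$txpos)
          s0 <- if (g$strand == "+") g$txStart + txp else
            g$txEnd - txp - L
          ch <- g$chrom
          bnd <- c(unlist(g$exonStarts), unlist(g$exonEnds))
        } else {
          ch <- sample(chrom_names, 1L)
          s0 <- sample.int(cfg$chrom_length - L - 200L, 1L) + 99L
          gi <- NA_integer_
          txp <- NA_real_
          bnd <- numeric(0)
        }
        e0 <- s0 + L
        if (s0 < 100 || e0 > cfg$chrom_length - 100) next
        if (!.clear_of(planted[[ch]], s0, e0, gap)) next
        if (length(bnd) > 0 && any(bnd > s0 - gap & bnd < e0 + gap)) next
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf(
          "infeasible placement: could not place a %d bp repeat (group '%s') with %d bp clearance",
          L, grp$name, gap))
      }
      res <- plant_repeat(seqs[[ch]], s0 + 1L, motif, copies, target)
      seqs[[ch]] <- .break_flanks(res$chars, s0 + 1L, e0, p)
      planted[[ch]] <- rbind(planted[[ch]],
                             data.frame(start = s0, end = e0))
      tract <- paste(seqs[[ch]][(s0 + 1L):e0], collapse = "")
      comp <- base_composition(tract)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = ch, srStart = s0, srEnd = e0, period = p,
        numRepeats = round_half_up(L / p, 1), consensusSize = p,
        perMatch = res$purity, perIndel = 0L,
        score = .span_score(.dna_chars(tract), 0L, L, p, scoring_params()),
        baseA = comp[["A"]], baseC = comp[["C"]], baseG = comp[["G"]],
        baseT = comp[["T"]],
        entropy = compute_entropy(tabulate(match(.dna_chars(tract),
                                                 VALID_BASES), 4L) / L),
        sequence = motif, group = grp$name,
        geneSymbol = if (is.na(gi)) NA_character_ else genes$geneSymbol[gi],
        txPosPlanted = txp, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    cbind(empty_str_records(),
          data.frame(group = character(0), geneSymbol = character(0),
                     txPosPlanted = numeric(0)))
  truth <- truth[order(truth$chrom, truth$srStart), , drop = FALSE]
  rownames(truth) <- NULL

  list(sequences = vapply(seqs, paste, character(1), collapse = ""),
       genes = genes, cpg = cpg, truth = truth, term_map = term_map,
       config = cfg)
}

#' Serialize truth records in the simpleRepeats dialect
#'
#' Produces (and optionally writes) a table ingestible by
#' [read_simple_repeats()], enabling detector-free pipeline runs against
#' known truth.
#'
#' @param truth Truth table from [simulate_genome()] (or any repeat table
#'   in the internal layout).
#' @param path Optional output path (tab-separated, with header).
#' @return The dialect data.frame, invisibly when written.
#' @export
truth_to_simple_repeats <- function(truth, path = NULL) {
  df <- data.frame(chrom = truth$chrom, chromStart = truth$srStart,
                   chromEnd = truth$srEnd, period = truth$period,
                   copyNum = truth$numRepeats,
                   consensusSize = truth$consensusSize,
                   perMatch = truth$perMatch, perIndel = truth$perIndel,
                   score = truth$score, A = truth$baseA, C = truth$baseC,
                   G = truth$baseG, T = truth$baseT,
                   entropy = truth$entropy, sequence = truth$sequence,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Weighted draw of a gene set with a planted enriched term
#'
#' Samples `set_size` genes without replacement, weighting genes of the
#' enriched term by `fold`, which emulates preferential acquisition of
#' regulatory-region repeats by that term's genes. Used for power checks
#' of the over-representation pipeline.
#'
#' @param background Character vector of all gene identifiers.
#' @param term_genes Genes carrying the enriched term.
#' @param set_size Size of the sampled set.
#' @param fold Sampling weight of term genes relative to the rest.
#' @return Character vector of sampled genes.
#' @export
plant_term_enrichment <- function(background, term_genes, set_size, fold) {
  w <- ifelse(background %in% term_genes, fold, 1)
  sample(background, set_size, prob = w)
}

#' Write simulation artifacts to disk
#'
#' Writes `genome.fa`, `genes.tsv` (genePred-like, with header),
#' `cpg.bed`, `repeats.tsv` (simpleRepeats dialect from truth),
#' `truth.tsv` and a `manifest.json` recording the configuration and seed.
#'
#' @param sim Output of [simulate_genome()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(sim$sequences)
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fa"))
  g <- sim$genes
  gp <- data.frame(name = g$transcriptId, chrom = g$chrom,
                   strand = g$strand, txStart = g$txStart, txEnd = g$txEnd,
                   cdsStart = g$cdsStart, cdsEnd = g$cdsEnd,
                   exonCount = vapply(g$exonStarts, length, integer(1)),
                   exonStarts = vapply(g$exonStarts, paste,
                                       character(1), collapse = ","),
                   exonEnds = vapply(g$exonEnds, paste,
                                     character(1), collapse = ","),
                   geneSymbol = g$geneSymbol, stringsAsFactors = FALSE)
  utils::write.table(gp, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$cpg, file.path(dir, "cpg.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth_to_simple_repeats(sim$truth, file.path(dir, "repeats.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- sim$config
  class(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
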