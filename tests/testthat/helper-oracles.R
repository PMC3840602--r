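# Independent brute-force oracles and shared fixtures for the test suite.

# Best indel-free alignment score over ALL spans of a sequence at a fixed
# period: direct O(n^2) enumeration, independent of the detector's
# seed/extend/trim machinery. The first `period` bases of a span always
# count as matches.
oracle_best_score <- function(seq, period, w = 2, pen = 7) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  best <- -Inf
  for (a in seq_len(n)) {
    sc <- 0
    for (b in a:n) {
      L <- b - a + 1
      if (L <= period) {
        sc <- w * L
      } else {
        hit <- chars[b] == chars[b - period] && valid[b] && valid[b - period]
        sc <- sc + if (hit) w else -pen
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# Exact hypergeometric upper tail P(X >= k) by enumerating every possible
# n-draw from an N-gene background with K term genes (N <= 12).
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute 1-based positions of a string with given bases
substitute_bases <- function(seq, pos, bases) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- bases
  paste(chars, collapse = "")
}

str_key <- function(d, start = "srStart", end = "srEnd",
                    period = "period") {
  paste(d$chrom %||% d$Chrom, d[[start]], d[[end]], d[[period]])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Default synthetic study fixture (seed 1, 100 genes) and its detection,
# computed once per test run.
.fixture_env <- new.env()
sim_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_genome(sim_config(seed = 1))
  }
  .fixture_env$sim
}
detect_fixture <- function() {
  if (is.null(.fixture_env$det)) {
    .fixture_env$det <- detect_strs(sim_fixture()$sequences)
  }
  .fixture_env$det
}
# the detector-free route: truth serialized and re-ingested
truth_strs_fixture <- function() {
  path <- tempfile(fileext = ".tsv")
  truth_to_simple_repeats(sim_fixture()$truth, path)
  on.exit(unlink(path))
  read_simple_repeats(path)
}
regions_fixture <- function() {
  sim <- sim_fixture()
  regions <- regulatory_window(
    select_canonical(exclude_nonprimary(sim$genes)),
    chrom_lengths = vapply(sim$sequences, nchar, integer(1)))
  suppressMessages(flag_cpg_overlap(regions, sim$cpg))
}
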