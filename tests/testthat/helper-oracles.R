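# Independent brute-force re-implementations used as oracles. These are
# deliberately written in the most literal style possible (character
# loops, exhaustive scans) and share no code with the package.

oracle_transition_score <- function(s) {
  ch <- strsplit(s, "")[[1]]
  score <- 0L
  if (length(ch) >= 2) {
    for (i in 2:length(ch)) if (ch[i] != ch[i - 1]) score <- score + 1L
  }
  score
}

oracle_classify <- function(s) {
  ch <- strsplit(s, "")[[1]]
  ch_no_n <- ch[ch != "N"]
  denom <- length(ch_no_n)
  pt <- if (denom > 0) sum(ch_no_n == "T") / denom else 0
  pc <- if (denom > 0) sum(ch_no_n == "C") / denom else 0
  pg <- if (denom > 0) sum(ch_no_n == "G") / denom else 0
  if (pt >= 0.1 && pc >= 0.1 && pg >= 0.1) return("HIGH_TCG")
  if (oracle_transition_score(s) > 12) return("FALSE_score_12plus")
  "TRUE"
}

# Longest run of `base` by checking every substring start/length.
oracle_longest_run <- function(s, base) {
  ch <- strsplit(s, "")[[1]]
  best <- 0L
  n <- length(ch)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && ch[j] == base) j <- j + 1L
    if (ch[i] == base) best <- max(best, j - i)
    i <- max(j, i + 1L)
  }
  best
}

# One round of PAS calling by exhaustive evaluation of every observed end
# position; returns NA when no candidate qualifies.
oracle_pas_round <- function(ends, called, strand, min_support, window,
                             min_separation) {
  cand <- sort(unique(ends))
  if (length(called) > 0) {
    ok <- sapply(cand, function(p) all(abs(p - called) > min_separation))
    cand <- cand[ok]
  }
  if (length(cand) == 0) return(NA_integer_)
  sup <- sapply(cand, function(p) sum(ends >= p - window &
                                        ends <= p + window))
  cand <- cand[sup >= min_support]
  sup <- sup[sup >= min_support]
  if (length(cand) == 0) return(NA_integer_)
  best <- cand[sup == max(sup)]
  if (length(best) > 1) {
    ex <- sapply(best, function(p) sum(ends == p))
    best <- best[ex == max(ex)]
  }
  if (length(best) > 1) {
    best <- if (strand == "+") min(best) else max(best)
  }
  best[1]
}

oracle_call_pas <- function(ends, strand = "+", min_support = 10,
                            window = 5, min_separation = 20) {
  called <- integer(0)
  repeat {
    s <- oracle_pas_round(ends, called, strand, min_support, window,
                          min_separation)
    if (is.na(s)) break
    called <- c(called, s)
  }
  as.integer(called)
}

random_tails <- function(n, max_len = 200, alphabet = c("A", "C", "G", "T", "N"),
                         a_bias = FALSE) {
  lens <- sample(0:max_len, n, replace = TRUE)
  k <- length(alphabet)
  prob <- if (a_bias) c(0.8, rep(0.2 / (k - 1), k - 1)) else NULL
  vapply(lens, function(l) {
    paste(sample(alphabet, l, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

# Small simulated datasets shared across test files, built once per run.
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(preset = "1C", seed = 11, n_genes = 30,
                       reads_per_gene_mean = 60, ...) {
  key <- paste(preset, seed, n_genes, reads_per_gene_mean, ..., sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_dataset(stage_preset(
      preset, seed = seed, n_genes = n_genes,
      reads_per_gene_mean = reads_per_gene_mean, ...))
  }
  .sim_cache[[key]]
}

truth_assignment <- function(sim) {
  stats::setNames(sim$truth$gene_id, sim$alignments$read_id)
}
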