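#' Simulation parameters for the maternal-mRNA remodeling model
#'
#' Bundles every knob of the ground-truth simulator: gene layout, per-gene
#' expression, the lognormal tail-length distribution, the fraction of
#' reads whose 3' end is a partially degraded UTR (PDIs), uridylation and
#' mono C/G residue rates, the N-length distribution placing the U run
#' within the tail, pass counts, sequencing error and UMI duplication.
#' Probabilities are fractions in `[0, 1]`; the same seed always produces
#' byte-identical output.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of non-overlapping genes placed on the chromosome.
#' @param chrom_length Chromosome length (nt); `NULL` sizes it to fit.
#' @param reads_per_gene_mean,reads_per_gene_size Negative-binomial mean
#'   and size for per-gene read counts.
#' @param prob_two_pas Probability a gene carries two polyadenylation
#'   sites.
#' @param prop_proximal_usage For two-site genes, probability a transcript
#'   uses the proximal site.
#' @param tail_log_mean,tail_log_sd Lognormal parameters of total tail
#'   length (nt); the geometric mean / median is `exp(tail_log_mean)`.
#' @param p_pdi Probability a read is drawn from the degraded-end regime.
#' @param pdi_offset_prob Geometric rate of the degradation offset; the
#'   offset upstream of the chosen site is `6 + rgeom(pdi_offset_prob)` nt
#'   (always beyond the 5-nt intact window, truncatable into the CDS).
#' @param p_u Probability a tail carries a consecutive-U run.
#' @param u_run_prob Geometric rate of the U-run length (`1 + rgeom`),
#'   supporting occasional runs beyond 20 nt.
#' @param n_length_zero_weight Point mass of N length 0 (the U run starts
#'   at the tail 5' origin).
#' @param n_length_prob Geometric rate of the nonzero N lengths, capped at
#'   15 nt.
#' @param p_end3_u Probability the U run is placed at the tail 3' terminus
#'   instead of internally.
#' @param c_rate,g_rate Per-base probability that an A position becomes a
#'   mono C / G residue.
#' @param error_rate Per-base substitution error rate in tail bases.
#' @param pass_mu,pass_size Negative-binomial parameters of consensus pass
#'   counts (floored at 1).
#' @param umi_dup_rate Poisson mean of extra PCR copies per molecule
#'   (0 disables UMI duplication).
#' @param barcode Sample barcode written into read names.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 50L,
                              chrom_length = NULL,
                              reads_per_gene_mean = 100,
                              reads_per_gene_size = 10,
                              prob_two_pas = 0.3,
                              prop_proximal_usage = 0.4,
                              tail_log_mean = log(33), tail_log_sd = 0.5,
                              p_pdi = 0.15, pdi_offset_prob = 0.02,
                              p_u = 0.3, u_run_prob = 0.4,
                              n_length_zero_weight = 0.3,
                              n_length_prob = 0.25,
                              p_end3_u = 0,
                              c_rate = 0.01, g_rate = 0.01,
                              error_rate = 0.001,
                              pass_mu = 30, pass_size = 10,
                              umi_dup_rate = 0,
                              barcode = "bc01") {
  cfg <- as.list(environment())
  probs <- c(cfg$prob_two_pas, cfg$prop_proximal_usage, cfg$p_pdi,
             cfg$p_u, cfg$p_end3_u, cfg$c_rate, cfg$g_rate,
             cfg$error_rate, cfg$n_length_zero_weight)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_genes >= 1L,
            cfg$tail_log_sd >= 0)
  structure(cfg, class = "sim_config")
}

#' Stage presets for the simulator
#'
#' Convenience parameter bundles emulating broad regimes of the
#' oocyte-to-embryo transition (not claims of fidelity to any real
#' sample): `GV` (germinal-vesicle oocyte: median tail 37 nt, ~15% PDIs,
#' low uridylation), `MII` (matured oocyte: long tails, median 63 nt),
#' `1C` (one-cell embryo: short tails, median 33 nt, ~60% PDIs, ~60%
#' uridylated tails) and `somatic` (~15% PDIs, sparse mostly mono non-A
#' residues).
#'
#' @param name One of `"GV"`, `"MII"`, `"1C"`, `"somatic"`.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A `sim_config`.
#' @export
stage_preset <- function(name, ...) {
  presets <- list(
    GV = list(tail_log_mean = log(37), p_pdi = 0.15, p_u = 0.10),
    MII = list(tail_log_mean = log(63), p_pdi = 0.15, p_u = 0.30),
    `1C` = list(tail_log_mean = log(33), p_pdi = 0.60, p_u = 0.60),
    somatic = list(tail_log_mean = log(70), p_pdi = 0.15, p_u = 0.15,
                   u_run_prob = 0.8)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  do.call(simulation_config, utils::modifyList(presets[[name]], list(...)))
}

# Transcript-coordinate gene architecture (0-based offsets from the TSS).
.gene_arch <- list(exon1_len = 300L, intron_len = 200L, exon2_len = 1500L,
                   cds_end_t = 1100L, span = 2000L)

#' Simulate a ground-truth dataset of aligned poly(A)-tailed reads
#'
#' Places `n_genes` two-exon genes (random strand) non-overlapping on one
#' chromosome, assigns each gene one or two polyadenylation sites in its
#' 3'-UTR, and emits reads under the remodeling model: intact reads end at
#' a site (within +/-1 nt of cleavage microheterogeneity), degraded reads
#' end `6 + Geom` nt
#' upstream of their site; every read carries a tail of lognormal total
#' length in which a consecutive-U run, mono C/G residues and substitution
#' errors are embedded. Alignments are constructed directly (single
#' M-block plus the tail as a terminal soft clip, reverse-complemented on
#' the minus strand), so the ground truth is exact. The true PIT/PDI
#' category is derived from the realized end position against all of the
#' gene's sites, keeping truth consistent with the classifier's geometry.
#'
#' @param config A [simulation_config()].
#' @return List with `config`, `genome` (named character vector of
#'   chromosome sequence), `genes` (gene-model tibble as
#'   [read_gene_models()] returns), `pas_truth` (tibble gene_id, chrom,
#'   strand, position, label), `alignments` (tibble in
#'   [read_alignments()] layout), and `truth` (per-read tibble with the
#'   true end position, category, site used, pre-error tail, U-run length
#'   and N length, pass count and UMI duplicate group).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  arch <- .gene_arch
  chrom <- "chrS"

  # --- gene placement -----------------------------------------------------
  gaps <- sample(200:800, config$n_genes, replace = TRUE)
  starts <- as.integer(1000L + cumsum(c(0L, gaps[-config$n_genes] +
                                          arch$span)) + gaps)
  ends <- starts + arch$span - 1L
  chrom_length <- config$chrom_length
  if (is.null(chrom_length)) chrom_length <- max(ends) + 1000L
  if (max(ends) + 500L > chrom_length) {
    stop("infeasible placement: ", config$n_genes,
         " genes need > ", max(ends) + 500L, " nt but chrom_length is ",
         chrom_length)
  }
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gene_id <- sprintf("G%04d", seq_len(config$n_genes))

  # transcript offset t (0-based from TSS) -> genomic coordinate
  t2g <- function(gi, t) {
    n <- max(length(gi), length(t))
    gi <- rep_len(gi, n)
    t <- rep_len(t, n)
    ifelse(strand[gi] == "+", starts[gi] + t, ends[gi] - t)
  }

  # --- polyadenylation sites (transcript offsets) -------------------------
  two <- stats::runif(config$n_genes) < config$prob_two_pas
  d_off <- sample(10:40, config$n_genes, replace = TRUE)
  dpas_t <- arch$span - 1L - d_off
  sep <- sample(100:400, config$n_genes, replace = TRUE)
  ppas_t <- ifelse(two, dpas_t - sep, NA_integer_)

  pas_truth <- do.call(rbind, lapply(seq_len(config$n_genes), function(gi) {
    tt <- c(if (two[gi]) ppas_t[gi], dpas_t[gi])
    lab <- if (two[gi]) c("pPAS", "dPAS") else "other"
    tibble::tibble(gene_id = gene_id[gi], chrom = chrom,
                   strand = strand[gi],
                   position = as.integer(t2g(gi, tt)), label = lab)
  }))

  # --- per-gene molecule counts -------------------------------------------
  n_mol <- stats::rnbinom(config$n_genes, mu = config$reads_per_gene_mean,
                          size = config$reads_per_gene_size)
  total <- sum(n_mol)
  gidx <- rep(seq_len(config$n_genes), n_mol)

  # --- 3' end positions (transcript offsets) ------------------------------
  use_prox <- two[gidx] &
    stats::runif(total) < config$prop_proximal_usage
  site_t <- ifelse(use_prox, ppas_t[gidx], dpas_t[gidx])
  degraded <- stats::runif(total) < config$p_pdi
  jitter <- sample(c(-1L, 0L, 1L), total, replace = TRUE,
                   prob = c(0.1, 0.8, 0.1))
  offset <- 6L + stats::rgeom(total, config$pdi_offset_prob)
  end_t <- ifelse(degraded, site_t - offset, site_t + jitter)
  end_t <- pmax(end_t, 400L)  # truncation floor inside the CDS
  end_t <- pmin(end_t, arch$span - 1L)

  # true category from realized geometry against all of the gene's sites
  all_sites_t <- lapply(seq_len(config$n_genes), function(gi) {
    c(if (two[gi]) ppas_t[gi], dpas_t[gi])
  })
  true_cat <- vapply(seq_len(total), function(i) {
    d <- end_t[i] - all_sites_t[[gidx[i]]]
    if (any(abs(d) <= 5L)) "PIT"
    else if (any(d < -5L)) "PDI"
    else "UNASSIGNED"
  }, character(1))

  # --- tails --------------------------------------------------------------
  tail_len <- pmax(1L, as.integer(round(stats::rlnorm(
    total, config$tail_log_mean, config$tail_log_sd))))
  has_u <- stats::runif(total) < config$p_u
  u_run <- 1L + stats::rgeom(total, config$u_run_prob)
  at_end3 <- stats::runif(total) < config$p_end3_u
  nlen <- ifelse(stats::runif(total) < config$n_length_zero_weight, 0L,
                 1L + pmin(stats::rgeom(total, config$n_length_prob), 14L))
  # clamp placements into the available length; internal runs keep >=1 A
  # at the 3' end so they stay internal
  nlen <- pmin(nlen, pmax(tail_len - 2L, 0L))
  u_run_int <- pmin(u_run, pmax(tail_len - 1L - nlen, 0L))
  u_run_end <- pmin(u_run, tail_len)
  place_int <- has_u & !at_end3 & u_run_int >= 1L
  place_end <- has_u & at_end3 & u_run_end >= 1L
  tail_seq <- strrep("A", tail_len)
  tail_seq[place_int] <- paste0(
    strrep("A", nlen[place_int]), strrep("T", u_run_int[place_int]),
    strrep("A", tail_len[place_int] - nlen[place_int] -
             u_run_int[place_int]))
  tail_seq[place_end] <- paste0(
    strrep("A", tail_len[place_end] - u_run_end[place_end]),
    strrep("T", u_run_end[place_end]))
  true_u_run <- ifelse(place_int, u_run_int, ifelse(place_end, u_run_end,
                                                    0L))
  true_nlen <- ifelse(place_int, nlen,
                      ifelse(place_end, tail_len - u_run_end,
                             NA_integer_))
  tail_pre_error <- tail_seq
  tail_seq <- .substitute_bases(tail_seq, "A", "C", config$c_rate)
  tail_seq <- .substitute_bases(tail_seq, "A", "G", config$g_rate)
  tail_seq <- .sequencing_errors(tail_seq, config$error_rate)

  # --- UMI duplication ----------------------------------------------------
  umi <- .encode_umi(seq_len(total))
  copies <- 1L + stats::rpois(total, config$umi_dup_rate)
  ridx <- rep(seq_len(total), copies)  # molecule index per emitted read
  n_reads <- length(ridx)
  pass <- pmax(1L, stats::rnbinom(n_reads, mu = config$pass_mu,
                                  size = config$pass_size))

  # --- alignment coordinates ----------------------------------------------
  span_len <- sample(400:1500, n_reads, replace = TRUE)
  gi <- gidx[ridx]
  start_t <- pmax(end_t[ridx] - span_len, 0L)
  ga <- t2g(gi, start_t)
  gb <- t2g(gi, end_t[ridx])
  aln_start <- as.integer(pmin(ga, gb))
  aln_end <- as.integer(pmax(ga, gb))

  read_id <- sprintf("m%06d", seq_len(n_reads))
  reads <- tibble::tibble(
    read_id = read_id,
    barcode = config$barcode,
    pass_count = as.integer(pass),
    umi = umi[ridx],
    chrom = chrom,
    strand = strand[gi],
    aln_start = aln_start,
    aln_end = aln_end,
    tail = tail_seq[ridx],
    gene_id = gene_id[gi]
  )
  reads$clip3 <- ifelse(reads$strand == "+", reads$tail, "")
  reads$clip5 <- ifelse(reads$strand == "-", revcomp(reads$tail), "")
  qv_char <- rawToChar(as.raw(33L + 30L))
  reads$clip3_qual <- strrep(qv_char, nchar(reads$clip3))
  reads$clip5_qual <- strrep(qv_char, nchar(reads$clip5))
  reads$is_supplementary <- FALSE

  truth <- tibble::tibble(
    read_id = read_id,
    molecule = ridx,
    gene_id = gene_id[gi],
    true_end = as.integer(ifelse(strand[gi] == "+", aln_end, aln_start)),
    category = true_cat[ridx],
    pas_used = as.integer(t2g(gi, site_t[ridx])),
    tail_pre_error = tail_pre_error[ridx],
    tail_length = tail_len[ridx],
    u_run_length = true_u_run[ridx],
    u_run_end3 = place_end[ridx],
    n_length = true_nlen[ridx],
    pass_count = as.integer(pass),
    umi = umi[ridx]
  )

  genome <- .random_genome(chrom_length)
  genes <- tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exon_starts = lapply(seq_len(config$n_genes), function(i) {
      if (strand[i] == "+") c(starts[i], starts[i] + 500L)
      else c(starts[i], ends[i] - 299L)
    }),
    exon_ends = lapply(seq_len(config$n_genes), function(i) {
      if (strand[i] == "+") c(starts[i] + 299L, ends[i])
      else c(starts[i] + 1499L, ends[i])
    }),
    cds_start = as.integer(ifelse(strand == "+", starts,
                                  ends - arch$cds_end_t)),
    cds_end = as.integer(ifelse(strand == "+", starts + arch$cds_end_t,
                                ends)),
    last_exon_start = as.integer(ifelse(strand == "+", starts + 500L,
                                        starts)),
    last_exon_end = as.integer(ifelse(strand == "+", ends,
                                      starts + 1499L)),
    span_start = starts, span_end = ends
  )

  list(config = config, genome = stats::setNames(genome, chrom),
       genes = genes, pas_truth = pas_truth, alignments = reads,
       truth = truth)
}

# Substitute `from` bases by `to` independently with probability `rate`.
.substitute_bases <- function(seqs, from, to, rate) {
  if (rate <= 0) return(seqs)
  n_hits <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_hits > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    at <- which(ch == from)
    if (length(at) == 0L) next
    k <- min(n_hits[i], length(at))
    ch[sample(at, k)] <- to
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Uniform substitution errors at `rate` per base.
.sequencing_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    at <- sample(length(ch), min(n_err[i], length(ch)))
    for (j in at) ch[j] <- sample(setdiff(bases, ch[j]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Deterministic unique 8-mer UMIs from molecule indices (base-4 encoding).
.encode_umi <- function(idx) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(idx))
  digits <- matrix("A", nrow = length(idx), ncol = 8L)
  v <- idx - 1L
  for (k in 8:1) {
    digits[, k] <- bases[v %% 4L + 1L]
    v <- v %/% 4L
  }
  apply(digits, 1L, paste, collapse = "")
}

.random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.gtf`, `reads.sam` (with `@HD`/`@SQ` header,
#' read names `read_id:barcode:pass[:umi]`, single M-block alignments and
#' the tail as a terminal soft clip), `truth.tsv` and `pas_truth.csv`.
#' Output bytes are a pure function of the simulation object.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "genes.gtf"),
             sam = file.path(dir, "reads.sam"),
             truth = file.path(dir, "truth.tsv"),
             pas = file.path(dir, "pas_truth.csv"))
  gset <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(gset, paths[["genome"]], width = 80L)
  writeLines(.gtf_lines(sim$genes), paths[["gtf"]])
  writeLines(.sam_lines(sim), paths[["sam"]])
  data.table::fwrite(sim$truth, paths[["truth"]], sep = "\t")
  data.table::fwrite(sim$pas_truth, paths[["pas"]], sep = ",")
  invisible(paths)
}

.gtf_lines <- function(genes) {
  unlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    attr_g <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gene_id,
                      g$gene_id)
    feat <- function(type, s, e) {
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s", g$chrom, type, s, e,
              g$strand, attr_g)
    }
    c(feat("gene", g$span_start, g$span_end),
      mapply(function(s, e) feat("exon", s, e), g$exon_starts[[1L]],
             g$exon_ends[[1L]]),
      feat("CDS", g$cds_start, g$cds_end))
  }))
}

.sam_lines <- function(sim) {
  a <- sim$alignments
  chrom <- names(sim$genome)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, nchar(sim$genome)))
  qname <- ifelse(is.na(a$umi) | a$umi == "",
                  paste(a$read_id, a$barcode, a$pass_count, sep = ":"),
                  paste(a$read_id, a$barcode, a$pass_count, a$umi,
                        sep = ":"))
  flag <- ifelse(a$strand == "+", 0L, 16L)
  width <- a$aln_end - a$aln_start + 1L
  body <- substr(rep(sim$genome, nrow(a)), a$aln_start, a$aln_end)
  qv_body <- strrep(rawToChar(as.raw(63L)), width)  # Q30
  pos_seq <- paste0(body, a$clip3)
  neg_seq <- paste0(a$clip5, body)
  seq <- ifelse(a$strand == "+", pos_seq, neg_seq)
  qual <- ifelse(a$strand == "+", paste0(qv_body, a$clip3_qual),
                 paste0(a$clip5_qual, qv_body))
  cigar <- ifelse(
    a$strand == "+",
    paste0(width, "M", ifelse(nchar(a$clip3) > 0L,
                              paste0(nchar(a$clip3), "S"), "")),
    paste0(ifelse(nchar(a$clip5) > 0L, paste0(nchar(a$clip5), "S"), ""),
           width, "M"))
  records <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s\tnp:i:%d",
                     qname, flag, chrom, a$aln_start, cigar, seq, qual,
                     a$pass_count)
  c(header, records)
}
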