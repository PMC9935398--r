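#' Geometric mean poly(A) tail length
#'
#' Gene tail lengths follow a lognormal-like distribution, so the gene-level
#' tail length is the geometric mean, `exp(mean(log(lengths)))`, over the
#' lengths (all >= 1 nt) of the gene's poly(A)+ reads.
#'
#' @param lengths Numeric vector of tail lengths, all >= 1.
#' @return The geometric mean, or `NA` for empty input.
#' @export
geometric_mean_tail_length <- function(lengths) {
  if (length(lengths) == 0L) return(NA_real_)
  stopifnot(all(lengths >= 1))
  exp(mean(log(lengths)))
}

#' Proportion of tails containing a given non-A residue
#'
#' Transcript level: the number of poly(A)+ tails containing the residue
#' (optionally restricted to 3'-end or internal placement) divided by the
#' total number of poly(A)+ tails.
#'
#' @param tail_seq Character vector of poly(A)+ tail sequences.
#' @param base `"T"`, `"C"` or `"G"`.
#' @param position `"any"`, `"end3"` or `"internal"`; placements per
#'   [residue_position_class()].
#' @return Fraction in `[0, 1]` (`NA` for empty input).
#' @export
transcript_nonA_proportion <- function(tail_seq, base, position = "any") {
  position <- match.arg(position, c("any", "end3", "internal"))
  if (length(tail_seq) == 0L) return(NA_real_)
  if (position == "any") {
    mean(count_base(tail_seq, base) > 0L)
  } else {
    mean(residue_position_class(tail_seq, base) == position)
  }
}

#' Gene-level proportion of tails with a given non-A residue
#'
#' As [transcript_nonA_proportion()] but computed per gene and reported
#' only for genes with at least `min_reads` poly(A)+ reads.
#'
#' @param records Tail-record tibble with `gene_id`, `tail_seq`.
#' @param base,position See [transcript_nonA_proportion()].
#' @param min_reads Minimum poly(A)+ reads for a gene to be reported.
#' @return Tibble `gene_id`, `n_reads`, `proportion`.
#' @export
gene_nonA_proportion <- function(records, base, position = "any",
                                 min_reads = 20L) {
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$gene_id),
    n_reads = dplyr::n(),
    proportion = transcript_nonA_proportion(.data$tail_seq, base, position),
    .groups = "drop"
  )
  out[out$n_reads >= min_reads, , drop = FALSE]
}

#' Proportion of polyadenylated degradation intermediates
#'
#' PDI proportion = #PDI / (#PDI + #PIT); UNASSIGNED reads never enter the
#' denominator. Undefined (NA) when no read is assigned.
#'
#' @param category Factor/character vector of PIT/PDI/UNASSIGNED calls.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
pdi_proportion <- function(category) {
  category <- as.character(category)
  n_pdi <- sum(category == "PDI")
  n_pit <- sum(category == "PIT")
  if (n_pdi + n_pit == 0L) return(NA_real_)
  n_pdi / (n_pdi + n_pit)
}

#' Gene-level PDI proportion
#'
#' Per gene, #PDI / (#PDI + #PIT), reported only when the denominator is at
#' least `min_reads`.
#'
#' @param assignments Tibble with `gene_id` and `category`.
#' @param min_reads Minimum #PDI + #PIT per gene.
#' @return Tibble `gene_id`, `n_assigned`, `pdi_proportion`.
#' @export
gene_pdi_proportion <- function(assignments, min_reads = 20L) {
  out <- dplyr::summarise(
    dplyr::group_by(assignments, .data$gene_id),
    n_assigned = sum(as.character(.data$category) %in% c("PDI", "PIT")),
    pdi_proportion = pdi_proportion(.data$category),
    .groups = "drop"
  )
  out[out$n_assigned >= min_reads, , drop = FALSE]
}

#' Average U length per tail
#'
#' The sum of U residues over all selected tails divided by the number of
#' selected tails. With `categories` supplied and `restrict = "PDI"`, both
#' numerator and denominator use only PDI reads.
#'
#' @param tail_seq Character vector of tail sequences.
#' @param categories Optional PIT/PDI/UNASSIGNED vector aligned with
#'   `tail_seq`.
#' @param restrict `"all"` or `"PDI"`.
#' @return Mean U count per tail (`NA` when the selection is empty).
#' @export
avg_u_length_per_tail <- function(tail_seq, categories = NULL,
                                  restrict = c("all", "PDI")) {
  restrict <- match.arg(restrict)
  if (restrict == "PDI") {
    stopifnot(!is.null(categories))
    tail_seq <- tail_seq[as.character(categories) == "PDI"]
  }
  if (length(tail_seq) == 0L) return(NA_real_)
  mean(count_base(tail_seq, "T"))
}

#' Tail-length comparison between APA isoforms
#'
#' For a gene with labeled proximal/distal sites, PIT reads are grouped by
#' their matched site and the geometric-mean tail length is reported for
#' each isoform, provided both isoforms have at least `min_reads` poly(A)+
#' reads.
#'
#' @param assignments [classify_reads()] output for the gene's reads.
#' @param tail_lengths Numeric vector aligned with `assignments` rows.
#' @param catalog Labeled catalog from [label_proximal_distal()].
#' @param min_reads Minimum reads per isoform.
#' @return One-row tibble `geo_mean_pPAS`, `geo_mean_dPAS`, `n_pPAS`,
#'   `n_dPAS`, or a zero-row tibble when the gene does not qualify.
#' @export
apa_isoform_tail_comparison <- function(assignments, tail_lengths, catalog,
                                        min_reads = 20L) {
  empty <- tibble::tibble(geo_mean_pPAS = numeric(0),
                          geo_mean_dPAS = numeric(0),
                          n_pPAS = integer(0), n_dPAS = integer(0))
  if (!"label" %in% names(catalog)) return(empty)
  p_site <- catalog$position[catalog$label == "pPAS"]
  d_site <- catalog$position[catalog$label == "dPAS"]
  if (length(p_site) != 1L || length(d_site) != 1L) return(empty)
  pit <- as.character(assignments$category) == "PIT"
  at_p <- pit & assignments$matched_pas == p_site
  at_d <- pit & assignments$matched_pas == d_site
  if (sum(at_p) < min_reads || sum(at_d) < min_reads) return(empty)
  tibble::tibble(
    geo_mean_pPAS = geometric_mean_tail_length(tail_lengths[at_p]),
    geo_mean_dPAS = geometric_mean_tail_length(tail_lengths[at_d]),
    n_pPAS = sum(at_p), n_dPAS = sum(at_d)
  )
}

#' Counts-per-million expression matrix
#'
#' CPM = 1e6 * (reads assigned to the gene) / (sum of all assigned reads),
#' per sample. Columns of the result each sum to one million. Expression
#' counting uses every read with at least one pass (no poly(A)+ filter).
#'
#' @param counts Numeric matrix (genes x samples) of read counts, with
#'   gene ids as rownames.
#' @return Matrix of CPM values with the same dimnames.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample with zero total reads")
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Two-group differential expression on CPM values
#'
#' Per gene: `log2FC = log2((mean_B + pseudocount) / (mean_A + pseudocount))`
#' and a two-sample t-test between the replicate CPM values (Student's
#' equal-variance by default, Welch optional). `alternative` follows
#' [stats::t.test()] conventions for B versus A. Genes with zero variance
#' in both groups and equal means get p = 1. Genes are flagged `up` when
#' `log2FC >= lfc_threshold` and `p < p_threshold`, `down` for the mirror
#' condition, `ns` otherwise.
#'
#' @param cpm_a,cpm_b Numeric matrices (genes x replicates), same genes in
#'   the same order; at least 2 replicates each.
#' @param pseudocount CPM pseudocount guarding against zero means.
#' @param alternative `"two.sided"` (default), `"greater"` (B > A) or
#'   `"less"`.
#' @param var_equal Use the pooled-variance Student's t-test.
#' @param lfc_threshold,p_threshold Flagging thresholds.
#' @return Tibble `gene_id`, `mean_A`, `mean_B`, `log2FC`, `p`, `flag`.
#' @export
differential_expression <- function(cpm_a, cpm_b, pseudocount = 1,
                                    alternative = c("two.sided", "greater",
                                                    "less"),
                                    var_equal = TRUE, lfc_threshold = 0.5,
                                    p_threshold = 0.05) {
  alternative <- match.arg(alternative)
  cpm_a <- as.matrix(cpm_a)
  cpm_b <- as.matrix(cpm_b)
  stopifnot(nrow(cpm_a) == nrow(cpm_b), ncol(cpm_a) >= 2L,
            ncol(cpm_b) >= 2L)
  mean_a <- rowMeans(cpm_a)
  mean_b <- rowMeans(cpm_b)
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  p <- vapply(seq_len(nrow(cpm_a)), function(i) {
    a <- cpm_a[i, ]
    b <- cpm_b[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) return(1)
      return(0)
    }
    stats::t.test(b, a, alternative = alternative,
                  var.equal = var_equal)$p.value
  }, numeric(1))
  flag <- rep("ns", nrow(cpm_a))
  flag[log2fc >= lfc_threshold & p < p_threshold] <- "up"
  flag[log2fc <= -lfc_threshold & p < p_threshold] <- "down"
  gene_id <- rownames(cpm_a)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(cpm_a)))
  tibble::tibble(gene_id = gene_id, mean_A = mean_a, mean_B = mean_b,
                 log2FC = log2fc, p = p,
                 flag = factor(flag, levels = c("up", "down", "ns")))
}

#' Tail-length histogram and median
#'
#' One-nt bins up to `max_len` (longer tails pooled in the overflow bin);
#' densities sum to 1. The reported median is the exact sample median of
#' the unpooled lengths.
#'
#' @param lengths Integer vector of poly(A)+ tail lengths.
#' @param max_len Largest individually binned length.
#' @return List with `histogram` (tibble `length`, `count`, `density`) and
#'   `median`.
#' @export
tail_length_histogram <- function(lengths, max_len = 250L) {
  lengths <- as.integer(lengths)
  pooled <- pmin(lengths, max_len)
  counts <- tabulate(pooled + 1L, nbins = max_len + 1L)  # lengths start at 0
  tibble_out <- tibble::tibble(
    length = 0:max_len,
    count = counts,
    density = if (length(lengths)) counts / length(lengths) else counts * 0
  )
  list(histogram = tibble_out,
       median = if (length(lengths)) stats::median(lengths) else NA_real_)
}

#' Gene-level summary table
#'
#' Combines the per-gene statistics over poly(A)+ tail records (and,
#' optionally, PIT/PDI assignments): read count, geometric-mean tail
#' length, proportions of tails carrying U/C/G, U run-group proportions,
#' average U per tail and PDI proportion. Genes below `min_reads` poly(A)+
#' reads are dropped.
#'
#' @param records Poly(A)+ tail-record tibble (`gene_id`, `tail_seq`).
#' @param assignments Optional tibble (`gene_id`, `read_id`, `category`)
#'   matched to `records` by `read_id`.
#' @param min_reads Gene inclusion threshold.
#' @return One row per qualifying gene.
#' @export
gene_summary <- function(records, assignments = NULL, min_reads = 20L) {
  grp <- dplyr::group_by(records, .data$gene_id)
  out <- dplyr::summarise(
    grp,
    n_polyA_reads = dplyr::n(),
    geo_mean_tail_length =
      geometric_mean_tail_length(nchar(.data$tail_seq)),
    prop_with_U = transcript_nonA_proportion(.data$tail_seq, "T"),
    prop_with_C = transcript_nonA_proportion(.data$tail_seq, "C"),
    prop_with_G = transcript_nonA_proportion(.data$tail_seq, "G"),
    prop_U1 = mean(run_group(.data$tail_seq, "T") == "U1"),
    prop_U2_5 = mean(run_group(.data$tail_seq, "T") == "U2-5"),
    prop_U6p = mean(run_group(.data$tail_seq, "T") == "U>=6"),
    avg_U_per_tail = avg_u_length_per_tail(.data$tail_seq),
    .groups = "drop"
  )
  out <- out[out$n_polyA_reads >= min_reads, , drop = FALSE]
  if (!is.null(assignments)) {
    pdi <- dplyr::summarise(
      dplyr::group_by(assignments, .data$gene_id),
      n_assigned = sum(as.character(.data$category) %in% c("PDI", "PIT")),
      pdi_proportion = pdi_proportion(.data$category),
      .groups = "drop"
    )
    pdi$pdi_proportion[pdi$n_assigned < min_reads] <- NA_real_
    out <- dplyr::left_join(out, pdi[, c("gene_id", "pdi_proportion")],
                            by = "gene_id")
  }
  out
}
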