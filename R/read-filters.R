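#' Keep poly(A)+ tail records
#'
#' A poly(A)+ read has a consensus pass count of at least `min_pass`
#' (default 10) and a tail of at least 1 nt; when the records carry a
#' `label` column only tails classified `TRUE` are retained. The operation
#' is idempotent and its output is a subset of its input.
#'
#' @param records Tail-record tibble (see [annotate_tail()]); must carry
#'   `pass_count` and `tail_seq`, optionally `label`.
#' @param min_pass Minimum pass count.
#' @return The filtered records.
#' @export
filter_polya_plus <- function(records, min_pass = 10L) {
  keep <- !is.na(records$pass_count) & records$pass_count >= min_pass &
    nchar(records$tail_seq) >= 1L
  if ("label" %in% names(records)) {
    keep <- keep & as.character(records$label) == "TRUE"
  }
  records[keep, , drop = FALSE]
}

#' Collapse PCR duplicates by UMI
#'
#' Keeps at most one record per (barcode, UMI, gene_id) key: the record
#' with the highest pass count, ties broken by the lexicographically
#' smallest read id, so the choice is deterministic. Records without a UMI
#' pass through unchanged (their count is reported via a warning).
#' Idempotent.
#'
#' @param records Tibble with columns `barcode`, `umi`, `gene_id`,
#'   `pass_count`, `read_id` (plus anything else, preserved).
#' @return Subset of `records` with unique keys.
#' @export
dedup_umi <- function(records) {
  if (nrow(records) == 0L) return(records)
  no_umi <- is.na(records$umi) | records$umi == ""
  if (any(no_umi)) {
    warning(sum(no_umi), " record(s) without a UMI passed through undeduplicated")
  }
  with_umi <- records[!no_umi, , drop = FALSE]
  if (nrow(with_umi) > 0L) {
    ord <- order(with_umi$barcode, with_umi$umi, with_umi$gene_id,
                 -with_umi$pass_count, with_umi$read_id, method = "radix")
    with_umi <- with_umi[ord, , drop = FALSE]
    key <- paste(with_umi$barcode, with_umi$umi, with_umi$gene_id,
                 sep = "\r")
    with_umi <- with_umi[!duplicated(key), , drop = FALSE]
  }
  out <- rbind(with_umi, records[no_umi, , drop = FALSE])
  out[order(out$read_id, method = "radix"), , drop = FALSE]
}

#' Does a read polyadenylate within its gene's last exon?
#'
#' True iff the read's polyadenylation site (its 3'-most aligned base in
#' transcript orientation) lies within the gene's terminal exon, inclusive
#' of both boundaries. Used to restrict fragmentation-prone libraries to
#' bona fide 3' ends.
#'
#' @param aln_start,aln_end Read alignment interval (1-based inclusive).
#' @param strand Gene strand.
#' @param last_exon_start,last_exon_end Terminal-exon interval.
#' @return Logical vector.
#' @export
last_exon_filter <- function(aln_start, aln_end, strand,
                             last_exon_start, last_exon_end) {
  pas <- read_end_position(aln_start, aln_end, strand)
  pas >= last_exon_start & pas <= last_exon_end
}

#' Assign reads to genes by overlap (plumbing fallback)
#'
#' A lightweight stand-in for an external feature-counting step when no
#' read-to-gene assignment table is supplied: a read is assigned to the
#' single gene on the same chromosome and strand whose span contains the
#' read's polyadenylation site or overlaps its aligned interval; reads
#' overlapping more than one such gene are left unassigned.
#'
#' @param reads Tibble with `read_id`, `chrom`, `strand`, `aln_start`,
#'   `aln_end`.
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @return Tibble `read_id`, `gene_id` (`NA` when unassigned/ambiguous).
#' @export
assign_gene <- function(reads, genes) {
  q <- GenomicRanges::GRanges(reads$chrom,
                              IRanges::IRanges(reads$aln_start,
                                               reads$aln_end),
                              strand = reads$strand)
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$span_start,
                                               genes$span_end),
                              strand = genes$strand)
  hits <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits)
  gene_id <- rep(NA_character_, nrow(reads))
  one <- which(tabulate(qh, nbins = nrow(reads)) == 1L)
  gene_id[qh[qh %in% one]] <- genes$gene_id[S4Vectors::subjectHits(hits)[qh %in% one]]
  tibble::tibble(read_id = reads$read_id, gene_id = gene_id)
}
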