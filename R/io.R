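#' Read primary alignments with their terminal soft clips
#'
#' Reads a SAM or BAM file and returns one row per primary alignment,
#' excluding unmapped, secondary, supplementary, QC-fail and duplicate
#' records (the samtools `-F 3844` set). The terminal soft-clip sequences
#' (and their base qualities) are cut out of each record using its CIGAR.
#' Read names of the form `name:barcode:pass` provide the barcode and pass
#' count; otherwise the pass count is taken from the `np` tag when present,
#' else left `NA` (such reads are removed later by pass-count filters). A
#' UMI is taken from a fourth colon field (`name:barcode:pass:umi`) when
#' present.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @return Tibble with columns `read_id`, `barcode`, `pass_count`, `umi`,
#'   `chrom`, `strand`, `aln_start`, `aln_end`, `clip5`, `clip3`,
#'   `clip5_qual`, `clip3_qual`, `is_supplementary` (always `FALSE`).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE,
    isDuplicate = FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq",
             "qual"),
    tag = "np"
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  if (n == 0L) {
    return(tibble::tibble(
      read_id = character(0), barcode = character(0),
      pass_count = integer(0), umi = character(0), chrom = character(0),
      strand = character(0), aln_start = integer(0), aln_end = integer(0),
      clip5 = character(0), clip3 = character(0), clip5_qual = character(0),
      clip3_qual = character(0), is_supplementary = logical(0)
    ))
  }
  cigar <- x$cigar
  bad <- is.na(cigar) | !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad)) {
    stop("malformed CIGAR for read(s): ",
         paste(utils::head(x$qname[bad], 5L), collapse = ", "))
  }
  ref_w <- cigar_reference_width(cigar)
  s5 <- as.integer(sub("^([0-9]+)S.*$", "\\1",
                       ifelse(grepl("^[0-9]+S", cigar), cigar, "0S")))
  s3 <- as.integer(sub("^.*?([0-9]+)S$", "\\1",
                       ifelse(grepl("[0-9]+S$", cigar), cigar, "0S")))
  seq <- as.character(x$seq)
  qual <- as.character(x$qual)
  len <- nchar(seq)
  meta <- parse_read_name(x$qname)
  np <- x$tag$np
  if (!is.null(np)) {
    use_np <- is.na(meta$pass_count) & !is.na(np)
    meta$pass_count[use_np] <- as.integer(np[use_np])
  }
  tibble::tibble(
    read_id = x$qname,
    barcode = meta$barcode,
    pass_count = meta$pass_count,
    umi = meta$umi,
    chrom = as.character(x$rname),
    strand = as.character(x$strand),
    aln_start = as.integer(x$pos),
    aln_end = as.integer(x$pos) + ref_w - 1L,
    clip5 = substr(seq, 1L, s5),
    clip3 = substr(seq, len - s3 + 1L, len),
    clip5_qual = substr(qual, 1L, s5),
    clip3_qual = substr(qual, len - s3 + 1L, len),
    is_supplementary = FALSE
  )
}

# Reference-space width of CIGAR strings (M/D/N/=/X consume the reference).
cigar_reference_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar)),
         function(ops) {
           w <- as.integer(sub("[A-Z=]$", "", ops))
           op <- sub("^[0-9]+", "", ops)
           sum(w[op %in% c("M", "D", "N", "=", "X")])
         }, integer(1))
}

# Split "name:barcode:pass[:umi]" read names; non-conforming names keep the
# whole string as read id with barcode/pass/umi missing.
parse_read_name <- function(qname) {
  parts <- strsplit(qname, ":", fixed = TRUE)
  np <- lengths(parts)
  pass_chr <- ifelse(np >= 3L, vapply(parts, function(p) p[3L],
                                      character(1)), NA_character_)
  pass <- suppressWarnings(as.integer(pass_chr))
  list(
    barcode = ifelse(np >= 3L, vapply(parts, function(p) p[2L],
                                      character(1)), NA_character_),
    pass_count = pass,
    umi = ifelse(np >= 4L, vapply(parts, function(p) p[4L], character(1)),
                 NA_character_)
  )
}

#' Read gene models from a GTF file
#'
#' Builds one gene model per `gene_id` from the exon (and optional CDS)
#' features: the exon list, gene span, CDS span and the terminal exon in
#' transcript orientation (largest-coordinate exon on the plus strand,
#' smallest on the minus). Genes without exon features are rejected.
#'
#' @param path GTF file.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `exon_starts`,
#'   `exon_ends` (list columns), `cds_start`, `cds_end` (NA when absent),
#'   `last_exon_start`, `last_exon_end`, `span_start`, `span_end`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  genes_in_file <- unique(gr$gene_id)
  missing_exons <- setdiff(genes_in_file, unique(ex$gene_id))
  if (length(missing_exons) > 0L) {
    stop("gene(s) without exon features: ",
         paste(missing_exons, collapse = ", "))
  }
  cds <- gr[gr$type == "CDS"]
  ex_df <- tibble::tibble(
    gene_id = ex$gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex)
  )
  ex_df <- ex_df[order(ex_df$gene_id, ex_df$start), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(ex_df, .data$gene_id),
    chrom = .data$chrom[1L],
    strand = .data$strand[1L],
    exon_starts = list(.data$start),
    exon_ends = list(.data$end),
    span_start = min(.data$start),
    span_end = max(.data$end),
    .groups = "drop"
  )
  last_idx <- ifelse(out$strand == "+",
                     lengths(out$exon_starts), 1L)
  out$last_exon_start <- mapply(function(s, i) s[i], out$exon_starts,
                                last_idx)
  out$last_exon_end <- mapply(function(e, i) e[i], out$exon_ends, last_idx)
  out$cds_start <- NA_integer_
  out$cds_end <- NA_integer_
  if (length(cds) > 0L) {
    cds_df <- tibble::tibble(gene_id = cds$gene_id,
                             start = GenomicRanges::start(cds),
                             end = GenomicRanges::end(cds))
    cds_rng <- dplyr::summarise(dplyr::group_by(cds_df, .data$gene_id),
                                cds_start = min(.data$start),
                                cds_end = max(.data$end), .groups = "drop")
    m <- match(out$gene_id, cds_rng$gene_id)
    out$cds_start <- cds_rng$cds_start[m]
    out$cds_end <- cds_rng$cds_end[m]
  }
  out[, c("gene_id", "chrom", "strand", "exon_starts", "exon_ends",
          "cds_start", "cds_end", "last_exon_start", "last_exon_end",
          "span_start", "span_end")]
}

#' Read a read-to-gene assignment table
#'
#' Consumes per-read feature-count output: whitespace/tab-delimited with
#' the read id in column 1, an assignment status in column 2 and the gene
#' id in column 4. Only rows whose status is `Assigned` contribute.
#' Duplicate read ids pointing at different genes are an error.
#'
#' @param path Text file with at least 4 columns.
#' @return Named character vector mapping read id to gene id.
#' @export
read_gene_assignment <- function(path) {
  if (file.size(path) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE,
                          na.strings = NULL)
  if (nrow(dt) == 0L) return(stats::setNames(character(0), character(0)))
  if (ncol(dt) == 1L) {
    dt <- data.table::fread(path, header = FALSE, sep = " ",
                            colClasses = "character", fill = TRUE,
                            na.strings = NULL)
  }
  bad <- which(rowSums(dt != "" & !is.na(dt)) < 4L)
  if (ncol(dt) < 4L || length(bad) > 0L) {
    stop("assignment table needs >= 4 columns; first offending line: ",
         if (length(bad)) bad[1L] else 1L)
  }
  keep <- dt[[2L]] == "Assigned"
  ids <- dt[[1L]][keep]
  genes <- dt[[4L]][keep]
  if (anyDuplicated(ids)) {
    conflicting <- tapply(genes, ids, function(g) length(unique(g)) > 1L)
    if (any(conflicting)) {
      stop("conflicting gene assignments for read(s): ",
           paste(utils::head(names(conflicting)[conflicting], 5L),
                 collapse = ", "))
    }
    keep_first <- !duplicated(ids)
    ids <- ids[keep_first]
    genes <- genes[keep_first]
  }
  stats::setNames(genes, ids)
}

tail_record_columns <- c(
  "barcode", "read_id", "gene_id", "pass_count", "const1", "count_A",
  "count_T", "count_C", "count_G", "count_nonA", "const0", "tail_seq",
  "mean_tail_qv"
)

#' Write / read the 13-column tail table
#'
#' The tail table is tab-separated without header, 13 columns in fixed
#' order: barcode, read id, gene id, pass count, the literal `1`, counts
#' of A/T/C/G, the non-A count, the literal `0`, the tail sequence (empty
#' field for 0-nt tails) and the mean tail base quality. Writing validates
#' the count invariants; a write/read round trip is the identity.
#'
#' @param records Tail-record tibble (see [annotate_tail()]).
#' @param path Output/input file.
#' @return `read_tail_records()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_tail_records <- function(records, path) {
  stopifnot(identical(names(records), tail_record_columns))
  n_base <- records$count_A + records$count_T + records$count_C +
    records$count_G
  n_n <- count_base(records$tail_seq, "N")
  ok <- n_base + n_n == nchar(records$tail_seq) &
    records$count_nonA == records$count_T + records$count_C +
      records$count_G
  if (!all(ok)) {
    stop("invalid tail record(s) at row(s): ",
         paste(utils::head(which(!ok), 5L), collapse = ", "))
  }
  data.table::fwrite(records, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_tail_records
#' @export
read_tail_records <- function(path) {
  dt <- data.table::fread(
    path, header = FALSE, sep = "\t",
    colClasses = list(character = c(1:3, 5, 11, 12), integer = c(4, 6:10),
                      numeric = 13),
    col.names = tail_record_columns, na.strings = NULL
  )
  out <- tibble::as_tibble(dt)
  out$tail_seq[is.na(out$tail_seq)] <- ""
  out
}

#' Write / read a polyadenylation-site catalog
#'
#' CSV with columns gene_id, chrom, strand, position, support, label
#' (pPAS / dPAS / other). Round trip is the identity.
#'
#' @param catalog Tibble with those six columns.
#' @param path CSV file.
#' @return `read_pas_catalog()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_pas_catalog <- function(catalog, path) {
  cols <- c("gene_id", "chrom", "strand", "position", "support", "label")
  stopifnot(all(cols %in% names(catalog)))
  out <- catalog[, cols]
  out$label <- as.character(out$label)
  data.table::fwrite(out, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' @rdname write_pas_catalog
#' @export
read_pas_catalog <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = c(1:3, 6),
                                            integer = 4:5))
  out <- tibble::as_tibble(dt)
  out$label <- factor(out$label, levels = c("pPAS", "dPAS", "other"))
  out
}
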