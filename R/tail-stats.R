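#' Annotate a poly(A) tail as a 13-field tail record
#'
#' Builds the per-read tail annotation used throughout the pipeline: base
#' counts, non-A count, the tail sequence itself and the mean base quality.
#' N bases are retained in `tail_seq` but counted in none of the four base
#' counts; `count_nonA = count_T + count_C + count_G`.
#'
#' @param read_id,gene_id,barcode Character vectors (recycled).
#' @param pass_count Integer vector of consensus pass counts.
#' @param tail_seq Character vector of tail sequences (already classified
#'   `TRUE`); `""` encodes a 0-nt tail.
#' @param mean_qv Optional numeric vector of mean tail base qualities
#'   (default 0 when absent).
#' @return A tail-record [tibble::tibble] with the 13 canonical columns
#'   (see [write_tail_records()]).
#' @export
annotate_tail <- function(read_id, gene_id, barcode, pass_count, tail_seq,
                          mean_qv = NULL) {
  n <- length(tail_seq)
  tail_seq <- as.character(tail_seq)
  if (is.null(mean_qv)) mean_qv <- rep(0, n)
  tibble::tibble(
    barcode = rep_len(as.character(barcode), n),
    read_id = rep_len(as.character(read_id), n),
    gene_id = rep_len(as.character(gene_id), n),
    pass_count = rep_len(as.integer(pass_count), n),
    const1 = "1",
    count_A = count_base(tail_seq, "A"),
    count_T = count_base(tail_seq, "T"),
    count_C = count_base(tail_seq, "C"),
    count_G = count_base(tail_seq, "G"),
    count_nonA = count_base(tail_seq, "T") + count_base(tail_seq, "C") +
      count_base(tail_seq, "G"),
    const0 = "0",
    tail_seq = tail_seq,
    mean_tail_qv = rep_len(as.numeric(mean_qv), n)
  )
}

#' Longest consecutive run of a base within each tail
#'
#' @param tail Character vector of tail sequences.
#' @param base Single base, one of `"T"`, `"C"`, `"G"`.
#' @return Integer vector: maximal run length (0 when absent).
#' @export
longest_run <- function(tail, base) {
  stopifnot(length(base) == 1L, base %in% c("T", "C", "G"))
  m <- gregexpr(paste0(base, "+"), as.character(tail))
  vapply(m, function(mm) {
    if (mm[1L] == -1L) 0L else max(attr(mm, "match.length"))
  }, integer(1))
}

#' Run-group label for the longest consecutive run of a base
#'
#' Tails are grouped by the length of their longest consecutive run of the
#' given base. For U (T): `U1`, `U2-5`, `U>=6`; for C: `C1`, `C2`, `C>=3`;
#' likewise for G. Tails without the base are `none`.
#'
#' @inheritParams longest_run
#' @return Factor with levels `none` plus the three group labels.
#' @export
run_group <- function(tail, base) {
  run <- longest_run(tail, base)
  ub <- if (base == "T") "U" else base
  if (base == "T") {
    lev <- c("none", "U1", "U2-5", "U>=6")
    lab <- ifelse(run == 0L, "none",
           ifelse(run == 1L, "U1", ifelse(run <= 5L, "U2-5", "U>=6")))
  } else {
    lev <- c("none", paste0(ub, c("1", "2", ">=3")))
    lab <- ifelse(run == 0L, "none",
           ifelse(run == 1L, paste0(ub, "1"),
           ifelse(run == 2L, paste0(ub, "2"), paste0(ub, ">=3"))))
  }
  factor(lab, levels = lev)
}

#' Classify residues of a base as 3'-end or internal
#'
#' A tail is first scanned for the base at its 3' terminus: if the terminal
#' base of the tail equals `base` the tail carries a 3'-end run of that base
#' (`end3`); otherwise, any occurrence elsewhere makes it `internal`; tails
#' without the base are `none`. With `collapse_end3_to_internal = TRUE`
#' every occurrence counts as internal, matching single-adapter protocols
#' that cannot resolve the tail 3' terminus.
#'
#' @inheritParams longest_run
#' @param collapse_end3_to_internal Report all occurrences as internal.
#' @return Factor with levels `none`, `end3`, `internal`.
#' @export
residue_position_class <- function(tail, base,
                                   collapse_end3_to_internal = FALSE) {
  stopifnot(length(base) == 1L, base %in% c("T", "C", "G"))
  tail <- as.character(tail)
  has <- count_base(tail, base) > 0L
  last <- substr(tail, nchar(tail), nchar(tail))
  cls <- ifelse(!has, "none", ifelse(last == base, "end3", "internal"))
  if (collapse_end3_to_internal) cls[cls == "end3"] <- "internal"
  factor(cls, levels = c("none", "end3", "internal"))
}

#' N length: offset of the unique longest U run from the tail 5' end
#'
#' The N length is the number of residues (of any kind) between the end of
#' the 3'-UTR — i.e. the tail 5' origin — and the first base of the longest
#' consecutive stretch of U residues in the tail. When two or more U runs
#' tie for longest the N length cannot be determined and `NA` is returned
#' (such tails are discarded from N-length analyses).
#'
#' @param tail Character vector of tail sequences, each containing at least
#'   one T.
#' @return Integer vector: 0-based offset of the unique longest T run, `NA`
#'   for ties.
#' @export
n_length <- function(tail) {
  tail <- as.character(tail)
  if (any(count_base(tail, "T") == 0L)) {
    stop("n_length() requires tails containing at least one U (T) residue")
  }
  m <- gregexpr("T+", tail)
  vapply(m, function(mm) {
    len <- attr(mm, "match.length")
    top <- which(len == max(len))
    if (length(top) > 1L) NA_integer_ else as.integer(mm[top] - 1L)
  }, integer(1))
}

#' Full residue profile of each tail
#'
#' Convenience wrapper combining tail length, longest runs, run groups,
#' position classes and (when defined) the N length for U residues.
#'
#' @param tail Character vector of tail sequences.
#' @param collapse_end3_to_internal See [residue_position_class()].
#' @return Tibble with one row per tail.
#' @export
tail_profile <- function(tail, collapse_end3_to_internal = FALSE) {
  tail <- as.character(tail)
  has_t <- count_base(tail, "T") > 0L
  nlen <- rep(NA_integer_, length(tail))
  if (any(has_t)) nlen[has_t] <- n_length(tail[has_t])
  tibble::tibble(
    tail_seq = tail,
    tail_length = nchar(tail),
    run_T = longest_run(tail, "T"),
    run_C = longest_run(tail, "C"),
    run_G = longest_run(tail, "G"),
    group_U = run_group(tail, "T"),
    group_C = run_group(tail, "C"),
    group_G = run_group(tail, "G"),
    pos_U = residue_position_class(tail, "T", collapse_end3_to_internal),
    pos_C = residue_position_class(tail, "C", collapse_end3_to_internal),
    pos_G = residue_position_class(tail, "G", collapse_end3_to_internal),
    n_length_U = nlen
  )
}
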