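#' Extract the candidate poly(A) tail of an aligned read
#'
#' The candidate tail is the terminal soft clip at the transcript 3' end:
#' the 3' soft clip for reads aligned to the plus strand, and the reverse
#' complement of the 5' soft clip for minus-strand alignments (a genomic
#' poly(A) tail appears as a leading T-run on the minus strand). The result
#' always reads 5'->3' along the transcript, so a genuine tail is A-rich.
#'
#' @param clip5,clip3 Terminal soft-clip sequences in reference orientation
#'   (possibly empty). Vectors are recycled to common length.
#' @param strand `"+"` or `"-"` per read.
#' @return Character vector of candidate tail sequences (may be `""` for
#'   0-nt tails).
#' @export
extract_candidate_tail <- function(clip5, clip3, strand) {
  n <- max(length(clip5), length(clip3), length(strand))
  clip5 <- rep_len(as.character(clip5), n)
  clip3 <- rep_len(as.character(clip3), n)
  strand <- rep_len(as.character(strand), n)
  stopifnot(all(strand %in% c("+", "-")))
  out <- clip3
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(clip5[neg])
  out
}

#' Reverse complement of DNA strings (keeps N)
#' @param x Character vector over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' Nucleotide transition score of a sequence
#'
#' Scanning 5'->3', each pair of adjacent residues scores 0 when equal and 1
#' when different; the score is the sum. Homopolymers (and sequences of
#' length <= 1) score 0. High scores indicate sequence too heterogeneous to
#' be a poly(A) tail.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Integer vector of scores.
#' @export
transition_score <- function(seq) {
  vapply(strsplit(as.character(seq), "", fixed = TRUE), function(ch) {
    n <- length(ch)
    if (n <= 1L) 0L else sum(ch[-1L] != ch[-n])
  }, integer(1))
}

count_base <- function(seq, base) {
  nchar(seq) - nchar(gsub(base, "", seq, fixed = TRUE))
}

#' Classify candidate poly(A) tails
#'
#' A candidate 3' soft clip is marked `HIGH_TCG` when the proportions of T,
#' C and G are each at least `prop_threshold` (default 0.1); otherwise
#' `FALSE_score_12plus` when its [transition_score()] exceeds `max_score`
#' (default 12); otherwise `TRUE`. Only `TRUE` tails enter downstream tail
#' analyses. Proportions are computed over non-N bases (N is a no-call);
#' the empty tail is `TRUE` with score 0 and zero proportions.
#'
#' @param seq Character vector of candidate tail sequences (DNA alphabet;
#'   U is represented as T).
#' @param prop_threshold Minimum T, C and G proportion for `HIGH_TCG`.
#' @param max_score Largest transition score still accepted as a tail.
#' @return A [tibble::tibble] with columns `seq`, `label` (factor with
#'   levels `TRUE`, `HIGH_TCG`, `FALSE_score_12plus`), `transition_score`,
#'   `prop_T`, `prop_C`, `prop_G`.
#' @export
classify_tail <- function(seq, prop_threshold = 0.1, max_score = 12L) {
  seq <- as.character(seq)
  denom <- nchar(seq) - count_base(seq, "N")
  prop_T <- ifelse(denom > 0, count_base(seq, "T") / denom, 0)
  prop_C <- ifelse(denom > 0, count_base(seq, "C") / denom, 0)
  prop_G <- ifelse(denom > 0, count_base(seq, "G") / denom, 0)
  score <- transition_score(seq)
  label <- rep("TRUE", length(seq))
  label[score > max_score] <- "FALSE_score_12plus"
  high <- prop_T >= prop_threshold & prop_C >= prop_threshold &
    prop_G >= prop_threshold
  label[high] <- "HIGH_TCG"  # checked first: overrides the score rule
  tibble::tibble(
    seq = seq,
    label = factor(label, levels = tail_labels()),
    transition_score = score,
    prop_T = prop_T, prop_C = prop_C, prop_G = prop_G
  )
}

#' Tail classification labels
#' @return Character vector of the three labels in precedence order of the
#'   accepting class last.
#' @export
tail_labels <- function() c("TRUE", "HIGH_TCG", "FALSE_score_12plus")

#' Split a G-tailed 3' segment into clean read and linker
#'
#' Some full-length library designs (FLAM-style G/I tailing) append a run
#' of about nine G residues between the
#' poly(A) tail and the UMI/barcode. Given the read segment that ends
#' immediately before the UMI/barcode, the trailing G-run of length g
#' determines the clean read: g < 7 discards the read; 7 <= g <= 16 strips
#' the whole run; g >= 17 strips exactly the 3'-most 17 Gs (surplus Gs are
#' retained as part of the tail).
#'
#' @param seq Character vector of 3' segments.
#' @return Character vector of clean sequences, `NA` for discarded reads.
#' @export
flam_split_g_tail <- function(seq) {
  seq <- as.character(seq)
  g <- nchar(seq) - nchar(sub("G*$", "", seq))
  out <- rep(NA_character_, length(seq))
  mid <- g >= 7L & g <= 16L
  out[mid] <- substr(seq[mid], 1L, nchar(seq[mid]) - g[mid])
  hi <- g >= 17L
  out[hi] <- substr(seq[hi], 1L, nchar(seq[hi]) - 17L)
  out
}
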