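#' Genomic polyadenylation position of a read
#'
#' The read's polyadenylation site is its 3'-most aligned base in transcript
#' orientation: `aln_end` for plus-strand genes, `aln_start` for minus.
#'
#' @param aln_start,aln_end Integer vectors of 1-based inclusive alignment
#'   coordinates.
#' @param strand Gene strand, `"+"` or `"-"` (recycled).
#' @return Integer vector of 1-based genomic coordinates.
#' @export
read_end_position <- function(aln_start, aln_end, strand) {
  n <- max(length(aln_start), length(aln_end), length(strand))
  aln_start <- rep_len(as.integer(aln_start), n)
  aln_end <- rep_len(as.integer(aln_end), n)
  strand <- rep_len(as.character(strand), n)
  stopifnot(all(strand %in% c("+", "-")), all(aln_start <= aln_end))
  ifelse(strand == "+", aln_end, aln_start)
}

#' Call polyadenylation sites for one gene from read 3' ends
#'
#' Greedy windowed-peak calling: candidate sites are the observed read-end
#' positions; the support of a site is the number of read ends within
#' `window` nt on either side (inclusive). Iteratively, among candidates
#' farther than `min_separation` nt (inclusive exclusion, |delta| <=
#' `min_separation` is too close) from every already-called site, the
#' maximum-support site is called if its support is at least `min_support`;
#' the loop stops when no candidate qualifies. Read ends are never removed
#' between rounds, so reported support counts overlap for nearby sites.
#' Ties on window support are broken by the larger exact-position read
#' count, then by the 5'-most coordinate in transcript orientation.
#'
#' @param end_positions Integer vector (multiset) of read 3'-end genomic
#'   positions from poly(A)+ reads of a single gene.
#' @param strand Gene strand (used only for the 5'-most tie-break).
#' @param min_support Minimum windowed read support to call a site.
#' @param window Half-width (nt) of the support window.
#' @param min_separation Minimum distance (nt) a new site must exceed from
#'   every called site.
#' @return Tibble with columns `position` and `support`, in call order
#'   (strongest first).
#' @export
call_pas <- function(end_positions, strand = "+", min_support = 10L,
                     window = 5L, min_separation = 20L) {
  ends <- as.integer(end_positions)
  ends <- ends[!is.na(ends)]
  if (length(ends) == 0L) {
    return(tibble::tibble(position = integer(0), support = integer(0)))
  }
  stopifnot(strand %in% c("+", "-"))
  tab <- table(ends)
  pos <- as.integer(names(tab))
  exact <- as.integer(tab)
  support <- vapply(pos, function(p) sum(abs(ends - p) <= window),
                    integer(1))
  avail <- rep(TRUE, length(pos))
  out_pos <- integer(0)
  out_sup <- integer(0)
  repeat {
    idx <- which(avail & support >= min_support)
    if (length(idx) == 0L) break
    best <- idx[support[idx] == max(support[idx])]
    if (length(best) > 1L) best <- best[exact[best] == max(exact[best])]
    if (length(best) > 1L) {
      best <- if (strand == "+") best[which.min(pos[best])]
              else best[which.max(pos[best])]
    }
    site <- pos[best[1L]]
    out_pos <- c(out_pos, site)
    out_sup <- c(out_sup, support[best[1L]])
    avail <- avail & abs(pos - site) > min_separation
  }
  tibble::tibble(position = out_pos, support = out_sup)
}

#' Label proximal/distal polyadenylation sites of a two-site gene
#'
#' For genes with exactly two called sites, the site proximal to the
#' transcription start site is `pPAS` and the distal one `dPAS`: on the
#' plus strand the smaller coordinate is proximal, on the minus strand the
#' larger. Catalogs with a different number of sites are returned with
#' `label = "other"` for every site.
#'
#' @param catalog Tibble from [call_pas()] (columns `position`, `support`).
#' @param strand Gene strand.
#' @return The catalog with an added `label` column in
#'   `{pPAS, dPAS, other}`.
#' @export
label_proximal_distal <- function(catalog, strand) {
  stopifnot(strand %in% c("+", "-"))
  catalog$label <- rep("other", nrow(catalog))
  if (nrow(catalog) == 2L) {
    prox <- if (strand == "+") which.min(catalog$position)
            else which.max(catalog$position)
    catalog$label[prox] <- "pPAS"
    catalog$label[-prox] <- "dPAS"
  }
  catalog$label <- factor(catalog$label, levels = c("pPAS", "dPAS", "other"))
  catalog
}

#' Classify reads of one gene as PIT, PDI or UNASSIGNED
#'
#' Against a (possibly reference) site catalog: a read whose 3' end lies
#' within `window` nt (inclusive) of a site is a polyadenylated intact
#' transcript (PIT) and is matched to the nearest site (exact distance ties
#' go to the 5'-most site); otherwise a read ending 5' upstream of at least
#' one site by more than `window` nt is a polyadenylated degradation
#' intermediate (PDI); remaining reads are UNASSIGNED. Genes with an empty
#' catalog yield all-UNASSIGNED. For PDIs the end region is annotated as
#' `CDS` when the end lies in the annotated CDS, `UTR3` when within the
#' terminal exon downstream of the CDS (or anywhere in the terminal exon if
#' no CDS is annotated), else `other`; PITs are `PAS_match`.
#'
#' @param read_id Character vector of read identifiers.
#' @param end_position Integer vector of read 3'-end genomic positions.
#' @param catalog Tibble with a `position` column (may have zero rows).
#' @param strand Gene strand.
#' @param window Matching half-width in nt.
#' @param cds_start,cds_end Optional CDS interval (NA when unannotated).
#' @param last_exon_start,last_exon_end Optional terminal-exon interval.
#' @return Tibble: `read_id`, `end_position`, `category` (factor
#'   PIT/PDI/UNASSIGNED), `matched_pas` (NA unless PIT), `end_region`.
#' @export
classify_reads <- function(read_id, end_position, catalog, strand,
                           window = 5L, cds_start = NA, cds_end = NA,
                           last_exon_start = NA, last_exon_end = NA) {
  stopifnot(strand %in% c("+", "-"))
  end_position <- as.integer(end_position)
  n <- length(end_position)
  sites <- as.integer(catalog$position)
  category <- rep("UNASSIGNED", n)
  matched <- rep(NA_integer_, n)
  if (length(sites) > 0L) {
    for (i in seq_len(n)) {
      d <- abs(end_position[i] - sites)
      if (min(d) <= window) {
        category[i] <- "PIT"
        best <- which(d == min(d))
        if (length(best) > 1L) {
          best <- if (strand == "+") best[which.min(sites[best])]
                  else best[which.max(sites[best])]
        }
        matched[i] <- sites[best[1L]]
      } else {
        upstream <- if (strand == "+") {
          any(end_position[i] < sites - window)
        } else {
          any(end_position[i] > sites + window)
        }
        if (upstream) category[i] <- "PDI"
      }
    }
  }
  region <- rep("other", n)
  region[category == "PIT"] <- "PAS_match"
  pdi <- which(category == "PDI")
  for (i in pdi) {
    e <- end_position[i]
    if (!is.na(cds_start) && !is.na(cds_end) && e >= cds_start &&
        e <= cds_end) {
      region[i] <- "CDS"
    } else if (!is.na(last_exon_start) && !is.na(last_exon_end) &&
               e >= last_exon_start && e <= last_exon_end) {
      downstream_of_cds <-
        if (is.na(cds_start) || is.na(cds_end)) TRUE
        else if (strand == "+") e > cds_end else e < cds_start
      if (downstream_of_cds) region[i] <- "UTR3"
    }
  }
  tibble::tibble(
    read_id = rep_len(as.character(read_id), n),
    end_position = end_position,
    category = factor(category, levels = c("PIT", "PDI", "UNASSIGNED")),
    matched_pas = matched,
    end_region = factor(region,
                        levels = c("PAS_match", "UTR3", "CDS", "other"))
  )
}
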