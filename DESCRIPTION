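Package: tailseqtk
Title: Poly(A) Tail Profiling from Aligned Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts candidate poly(A) tails from the terminal soft clips of
    aligned long circular-consensus reads, classifies them (TRUE / HIGH_TCG /
    FALSE_score_12+), computes per-tail non-A residue statistics (longest U/C/G
    runs, 3'-end versus internal placement, N length), calls polyadenylation
    sites per gene by a greedy windowed-peak rule, classifies reads into
    polyadenylated intact transcripts (PITs) and polyadenylated degradation
    intermediates (PDIs), and summarises genes (geometric-mean tail length,
    uridylation and PDI proportions, CPM expression, two-group differential
    expression). Includes a ground-truth simulator of the maternal-mRNA
    remodeling model (deadenylation, uridylation, re-polyadenylation) so every
    stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
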