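---
title: "Methods: poly(A) tail profiling and maternal-mRNA remodeling statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) tail profiling and maternal-mRNA remodeling statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Full-length circular-consensus (CCS) long reads of polyadenylated cDNA
carry the complete poly(A) tail, but an aligner cannot place the tail on
the genome: it ends up as a *terminal soft clip*. `tailseqtk` turns
aligned reads (SAM/BAM) plus a gene annotation (GTF) into per-read tail
annotations and gene-level statistics, with particular attention to two
signatures of maternal-mRNA remodeling during the oocyte-to-embryo
transition: *polyadenylated degradation intermediates* (PDIs — transcripts
whose 3′-UTR was partially degraded and then re-polyadenylated) and
*non-A residues* (U, C, G) embedded in tails by uridylation and
guanylation.

# Tail extraction and classification

The candidate tail of a primary alignment (`-F 3844` exclusion set; reads
with supplementary flags are never used) is its 3′-terminal soft clip; on
minus-strand alignments the 5′ soft clip is reverse-complemented so tails
always read 5′→3′ along the transcript. Two filters separate real tails
from adapters, unremoved genomic sequence and chimeric clips:

* **HIGH_TCG** — the proportions of T, C and G in the clip are each
  ≥ 0.1. Genuine tails are A-dominated with sparse non-A residues, so a
  clip rich in all three other bases is not a tail. Proportions are
  computed over non-N bases; N is a no-call and counts toward nothing.
* **FALSE_score_12+** — the *transition score*, the number of adjacent
  unequal base pairs scanning 5′→3′, exceeds 12. A homopolymer scores 0;
  heavily interleaved sequence scores high. The score is computed on the
  full clip.

Clips failing neither test are **TRUE** and proceed to annotation; the
empty clip is a valid 0-nt tail and classifies TRUE (it carries no
contrary evidence). HIGH_TCG is tested before the score rule, so a clip
satisfying both is HIGH_TCG.

A **poly(A)+ read** has pass count ≥ 10 (consensus accuracy grows with
passes; below ~10 passes individual tail bases are unreliable), a tail of
≥ 1 nt and a TRUE classification. All tail-level statistics use poly(A)+
reads; expression counting (CPM) deliberately uses every read with ≥ 1
pass, since a read's existence is informative even when its tail bases
are not.

Protocol-specific steps: UMI-carrying libraries are deduplicated to one
record per (barcode, UMI, gene) — the record with the highest pass count,
ties broken by smallest read id, a deterministic proxy for consensus
quality. Fragmentation-prone libraries can be restricted to reads whose
polyadenylation site falls inside the assigned gene's terminal exon.
G-tailed libraries (a ~9-G linker between tail and UMI) are cleaned by a
three-branch rule on the trailing G-run length *g*: discard when *g* < 7,
strip the whole run when 7 ≤ *g* ≤ 16, strip exactly 17 Gs when *g* ≥ 17.

# Residue statistics

Per tail we report base counts (the 13-column tail table), the longest
consecutive run of each non-A base, its run group (U: 1 / 2–5 / ≥6;
C and G: 1 / 2 / ≥3), and whether the base occurs at the tail's 3′
terminus (`end3`: the tail's last base, read as a maximal terminal run) or
only internally. Single-adapter protocols that cannot resolve the tail 3′
end report everything as internal via `collapse_end3_to_internal`.

The **N length** of a uridylated tail is the number of residues (of any
kind) between the tail's 5′ origin — the end of the 3′-UTR — and the
first base of the tail's *unique* longest U run; when two runs tie for
longest the quantity is undefined and the tail is dropped from N-length
analyses. A short N length is the footprint of uridylation acting on a
deadenylated substrate before re-adenylation.

# Polyadenylation sites and PIT/PDI classification

A read's polyadenylation position is its 3′-most aligned base in
transcript orientation. Sites are called per gene by a greedy windowed
peak rule over observed end positions: support of a candidate is the
number of read ends within ±5 nt (inclusive); the best-supported
candidate with support ≥ 10 is called, candidates within 20 nt
(inclusive) of a called site are excluded, and the loop repeats until no
candidate qualifies. Reads are never consumed between rounds. Ties on
window support go to the larger exact-end count, then the 5′-most
coordinate. Candidates are restricted to observed end positions — this
keeps the search finite and, in practice, any high-support position is
represented by a nearby observed end. For genes with exactly two sites
the one nearer the transcription start is labeled `pPAS`, the other
`dPAS`.

Each poly(A)+ read is then classified against a catalog: **PIT** when its
end is within ±5 nt (inclusive) of a site, matched to the nearest site
(ties to the 5′-most); otherwise **PDI** when the end lies > 5 nt
5′-upstream of at least one site; otherwise **UNASSIGNED** (discarded
from PDI analyses, never counted in denominators). The PDI proportion is
#PDI / (#PDI + #PIT); gene-level values require ≥ 20 assigned reads.

A catalog called on one sample can serve as the *reference* for
classifying other samples. This matters when degradation is heavy: at a
60% PDI fraction the degraded ends themselves can pile up past the
support threshold and be called as spurious sites, absorbing nearby PDIs
into PITs. Calling the catalog on a low-degradation reference sample
(here, the GV-stage regime) and classifying every stage against it avoids
that bias; the package treats reference-catalog reuse as a first-class
mode and the acceptance workflow uses it.

# Gene-level summaries

Tail length per gene is the **geometric mean** over its poly(A)+ reads —
per-gene tail lengths are lognormal-like, so the geometric mean (the
lognormal median) is the natural location. Non-A proportions count
*tails containing* the residue, not residues. The average U length per
tail is ΣU / N over the selected reads (optionally PDIs only, in both
numerator and denominator). Gene-level outputs require ≥ 20 reads —
below that the proportions are too noisy to interpret.

CPM is `1e6 × count / total` per sample; columns sum to one million by
construction. Differential expression compares replicate CPM values per
gene with a two-sample t-test on a `log2((mean_B + ε)/(mean_A + ε))`
fold change, ε = 1 CPM by default so zero-CPM genes yield finite fold
changes. The test defaults to Student's (pooled variance), two-sided;
one-sided alternatives and Welch's variant are flags. A fixed two-sided
default was chosen because the flagging rule (|log2FC| ≥ 0.5, p < 0.05)
is symmetric in direction; choosing the tail per gene from the observed
direction would double the type-I rate, and the null-calibration test in
this package verifies the default's 5% level empirically. Genes with zero
variance in both groups and equal means get p = 1.

# The synthetic-data generator

Controlled-access single-oocyte/embryo data cannot ship with a package,
so every stage of the pipeline is validated against a generator that
emulates the remodeling model: transcripts are cleaved at one or two
polyadenylation sites per gene; a fraction `p_pdi` of molecules is
partially degraded before re-polyadenylation; tails carry internal or
3′-terminal U runs, sparse mono C/G residues and substitution errors.
Reads are emitted *pre-aligned* — SAM records are constructed directly
with the tail as a terminal soft clip — so ground truth is exact and no
aligner is needed.

Key defaults, chosen once as representative of this data type:

| parameter | default | rationale |
|---|---|---|
| tail length | lognormal, median `exp(tail_log_mean)`, log-sd 0.5 | per-gene tail lengths are lognormal-like; log-sd 0.5 spans ~13–85 nt around a 33-nt median |
| end microheterogeneity | ±1 nt (80/10/10%) | cleavage-site wobble of intact 3′ ends |
| degradation offset | 6 + Geometric(0.02) nt upstream | always beyond the 5-nt intact window; mean ~56 nt, long tail reaching the CDS; no shared hotspots |
| U run length | 1 + Geometric(0.4) | mostly short runs with a tail beyond 20 nt |
| N length | 30% at 0, else 1 + Geometric(0.25) capped at 15 | uridylation acts at or near the deadenylated 3′-UTR end |
| mono C/G rate | 0.01 per A position each | sparse guanylation/cytidylation |
| tail error rate | 0.001 substitutions/base | ≈ Q30 consensus accuracy at ≥10 passes |
| pass count | NegBin(μ = 30, size = 10), floor 1 | most reads clear the 10-pass filter, a few percent do not |

The drawn lognormal length is the *total* tail length; the U run and
mono residues replace positions within it (the
deadenylate–uridylate–re-adenylate reading of the model). This keeps the
realized tail-length distribution exactly lognormal, so tail-length
recovery is well defined. A read's true PIT/PDI label is derived from its
realized end position against *all* of its gene's sites, so truth is
always geometrically consistent with the classifier's definitions (a
degraded end landing within 5 nt of the proximal site *is* an intact
proximal-isoform end).

Stage presets bundle regimes (medians 37/63/33 nt and PDI/uridylation
levels 15%/15%/60% for GV/MII/1C; a somatic preset with sparse mono
residues); they are conveniences, not claims of fidelity to any real
sample.

What the generator does **not** emulate: indels in tails (substitutions
only, keeping true length exact), base-caller error correlation,
transcription during the stages modeled (all reads are "maternal"),
intron-aware alignment blocks (reads are single-block alignments over a
two-exon gene model), shared degradation hotspots, and
adapter/demultiplexing artifacts. Passing tests therefore demonstrate
correctness of the *computations* under a faithful generative model of
read 3′ ends and tails — not robustness to every artifact of real
libraries.

# Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive (SAM convention) throughout.
* "Within 5 nt" and "within 20 nt" are inclusive (|Δ| ≤ 5 matches;
  |Δ| ≤ 20 blocks a new site).
* All tie-breaks are deterministic (exact-count then 5′-most for site
  calling; nearest then 5′-most for PIT matching; max pass then smallest
  read id for UMI dedup).
* Empty inputs: an empty tail is TRUE with score 0; an empty pileup
  yields an empty catalog; a gene without a catalog yields all
  UNASSIGNED; empty selections make proportions and geometric means `NA`
  rather than 0.
* `n_length()` on a U-free tail is an error by contract (the caller
  filters first); ties return `NA`.

# Validation scale

The test suite and acceptance workflow run at desk scale, sized so the
statistical checks are sharp but fast: classifier and run-statistics
oracles on 10,000 random sequences; the site caller against a per-round
exhaustive oracle on 1,000 random pileups; parameter recovery on 200
genes × ~100 reads per stage (~20,000 reads), where binomial error on
the PDI and uridylation fractions is ~0.4% and the per-gene
geometric-mean median lands within 5% of the generator's 33-nt median;
differential-expression calibration on 2,000 null genes. The analysis
scripts under `analysis/` use 100-gene datasets for the same reason.

# Known limitations

* The overlap-based gene assigner is plumbing for annotation-only runs;
  a dedicated feature-counting tool's per-read table is the preferred
  input and is consumed directly.
* HIGH_TCG reads are dropped, never rescued; no quality-aware tail
  correction is attempted.
* Site calling reports no confidence measure beyond raw window support.
* Raw p values only; no multiple-testing correction is applied (flagging
  thresholds operate on raw p).
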