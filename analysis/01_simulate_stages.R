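#!/usr/bin/env Rscript
# Simulate one dataset per developmental regime (GV and MII oocytes,
# one-cell embryo) over a shared 100-gene universe, and write the raw
# artifacts (genome FASTA, GTF, SAM alignments, ground truth) under
# scratch/sim/<stage>/. The three stages share the same seed-derived gene
# layout, so polyadenylation sites called in one stage can serve as the
# reference catalog for the others — mirroring how a low-degradation
# reference sample anchors PIT/PDI classification of remodeled samples.

suppressMessages(library(tailseqtk))

seed <- 2024L
n_genes <- 100L
stages <- c("GV", "MII", "1C")

for (stage in stages) {
  sim <- simulate_dataset(stage_preset(stage, seed = seed,
                                       n_genes = n_genes))
  out <- file.path("scratch", "sim", stage)
  write_simulated_dataset(sim, out)
  n_pdi <- sum(sim$truth$category == "PDI")
  message(sprintf(
    "%-3s: %5d reads, %3.0f%% degraded ends (truth), %d PAS sites -> %s",
    stage, nrow(sim$alignments),
    100 * n_pdi / nrow(sim$truth), nrow(sim$pas_truth), out))
}
message("done: raw simulated datasets under scratch/sim/")
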