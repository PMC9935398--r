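test_that("same seed gives byte-identical simulator output", {
  cfg <- simulation_config(seed = 5, n_genes = 8, reads_per_gene_mean = 30,
                           umi_dup_rate = 0.3)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_simulated_dataset(simulate_dataset(cfg), d1)
  write_simulated_dataset(simulate_dataset(cfg), d2)
  for (f in c("genome.fa", "genes.gtf", "reads.sam", "truth.tsv",
              "pas_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("bytes of", f))
  }
  # and a different seed differs
  d3 <- file.path(tempdir(), "simC")
  cfg2 <- simulation_config(seed = 6, n_genes = 8,
                            reads_per_gene_mean = 30, umi_dup_rate = 0.3)
  write_simulated_dataset(simulate_dataset(cfg2), d3)
  expect_false(identical(readLines(file.path(d1, "reads.sam")),
                         readLines(file.path(d3, "reads.sam"))))
})

test_that("degenerate config yields only intact pure-A tails", {
  cfg <- simulation_config(seed = 2, n_genes = 10,
                           reads_per_gene_mean = 40, p_pdi = 0, p_u = 0,
                           c_rate = 0, g_rate = 0, error_rate = 0)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$category == "PIT"))
  tails <- extract_candidate_tail(sim$alignments$clip5,
                                  sim$alignments$clip3,
                                  sim$alignments$strand)
  expect_true(all(grepl("^A*$", tails)))
  expect_true(all(classify_tail(tails)$label == "TRUE"))
})

test_that("simulated SAM round trips through the alignment reader", {
  sim <- cached_sim(n_genes = 10, reads_per_gene_mean = 25,
                    umi_dup_rate = 0.2)
  dir <- file.path(tempdir(), "simRT")
  paths <- write_simulated_dataset(sim, dir)
  aln <- read_alignments(paths[["sam"]])
  expect_identical(nrow(aln), nrow(sim$alignments))
  ord <- match(sub(":.*$", "", aln$read_id), sim$alignments$read_id)
  expect_identical(aln$aln_start, sim$alignments$aln_start[ord])
  expect_identical(aln$aln_end, sim$alignments$aln_end[ord])
  expect_identical(aln$clip3, sim$alignments$clip3[ord])
  expect_identical(aln$clip5, sim$alignments$clip5[ord])
  expect_identical(aln$pass_count, sim$alignments$pass_count[ord])
  expect_identical(aln$umi, sim$alignments$umi[ord])
  # gene models parsed from the emitted GTF agree with the simulated ones
  gm <- read_gene_models(paths[["gtf"]])
  ordg <- match(gm$gene_id, sim$genes$gene_id)
  expect_identical(gm$last_exon_start, sim$genes$last_exon_start[ordg])
  expect_identical(gm$last_exon_end, sim$genes$last_exon_end[ordg])
  expect_identical(gm$strand, sim$genes$strand[ordg])
})

test_that("UMI deduplication restores pre-duplication molecule counts", {
  sim <- cached_sim(n_genes = 10, reads_per_gene_mean = 25,
                    umi_dup_rate = 0.2)
  ex <- extract_tails(sim$alignments, assignment = truth_assignment(sim),
                      min_pass = 1L, dedup = TRUE)
  per_gene <- table(ex$all_records$gene_id)
  molecules <- unique(sim$truth[, c("molecule", "gene_id")])
  want <- table(molecules$gene_id)
  expect_identical(as.vector(per_gene[names(want)]), as.vector(want))
})

test_that("stage presets document their regimes and reject unknowns", {
  p1c <- stage_preset("1C")
  expect_equal(exp(p1c$tail_log_mean), 33)
  expect_equal(p1c$p_pdi, 0.6)
  expect_equal(p1c$p_u, 0.6)
  gv <- stage_preset("GV")
  expect_equal(exp(gv$tail_log_mean), 37)
  expect_equal(gv$p_pdi, 0.15)
  som <- stage_preset("somatic")
  expect_equal(som$p_pdi, 0.15)
  expect_error(stage_preset("blastoid"), "available")
  # overrides pass through
  expect_identical(stage_preset("GV", n_genes = 123L)$n_genes, 123L)
})

test_that("infeasible gene placement is rejected", {
  cfg <- simulation_config(seed = 1, n_genes = 20, chrom_length = 10000)
  expect_error(simulate_dataset(cfg), "infeasible placement")
})

test_that("truth labels are geometrically consistent with the catalog", {
  sim <- cached_sim()
  # every truth PDI ends >5 nt upstream of at least one true site and
  # >5 nt away from all sites of its gene
  sites <- split(sim$pas_truth$position, sim$pas_truth$gene_id)
  strands <- sim$genes$strand[match(names(sites), sim$genes$gene_id)]
  ok <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    ss <- sites[[tr$gene_id]]
    st <- strands[match(tr$gene_id, names(sites))]
    if (tr$category == "PDI") {
      all(abs(tr$true_end - ss) > 5) &&
        (if (st == "+") any(tr$true_end < ss - 5)
         else any(tr$true_end > ss + 5))
    } else if (tr$category == "PIT") {
      min(abs(tr$true_end - ss)) <= 5
    } else {
      TRUE
    }
  }, logical(1))
  expect_true(all(ok))
})
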