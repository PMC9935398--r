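test_that("geometric mean tail length matches closed forms", {
  expect_equal(geometric_mean_tail_length(c(7, 7, 7)), 7)
  expect_equal(geometric_mean_tail_length(c(10, 1000)), 100)
  set.seed(3)
  x <- sample(1:300, 50, replace = TRUE)
  expect_equal(geometric_mean_tail_length(x),
               geometric_mean_tail_length(rev(x)))
  expect_true(is.na(geometric_mean_tail_length(numeric(0))))
  # high-precision oracle and bounds
  expect_equal(geometric_mean_tail_length(x), prod(x^(1 / length(x))),
               tolerance = 1e-9)
  expect_true(geometric_mean_tail_length(x) >= min(x))
  expect_true(geometric_mean_tail_length(x) <= max(x))
})

test_that("non-A proportions count tails, not residues", {
  tails <- c("AATAA", "AAAAT", "AAAAA")
  expect_equal(transcript_nonA_proportion(tails, "T"), 2 / 3)
  expect_equal(transcript_nonA_proportion(tails, "G"), 0)
  expect_equal(transcript_nonA_proportion(tails, "T", "end3"), 1 / 3)
  expect_equal(transcript_nonA_proportion(tails, "T", "internal"), 1 / 3)
  # gene-level gate at 20 reads
  rec <- tibble::tibble(gene_id = rep(c("g1", "g2"), c(20, 19)),
                        tail_seq = rep("AT", 39))
  out <- gene_nonA_proportion(rec, "T")
  expect_identical(out$gene_id, "g1")
})

test_that("PDI proportion excludes unassigned reads from the denominator", {
  cats <- rep(c("PDI", "PIT", "UNASSIGNED"), c(6, 4, 2))
  expect_equal(pdi_proportion(cats), 0.6)
  expect_equal(pdi_proportion(rep("PIT", 5)), 0)
  expect_true(is.na(pdi_proportion(rep("UNASSIGNED", 5))))
})

test_that("average U length per tail supports the PDI-only restriction", {
  tails <- c("ATTA", "AAAA", "ATAA")
  expect_equal(avg_u_length_per_tail(tails), 1)
  expect_equal(avg_u_length_per_tail(rep("AAA", 3)), 0)
  cats <- c("PDI", "PIT", "PDI")
  expect_equal(avg_u_length_per_tail(tails, cats, restrict = "PDI"), 1.5)
})

test_that("APA comparison requires 20 reads on both isoforms", {
  catalog <- label_proximal_distal(
    tibble::tibble(position = c(1000L, 1500L), support = c(30L, 40L)), "+")
  asg <- tibble::tibble(
    category = rep("PIT", 55),
    matched_pas = rep(c(1000L, 1500L), c(25, 30)))
  lens <- rep(c(20, 80), c(25, 30))
  out <- apa_isoform_tail_comparison(asg, lens, catalog)
  expect_identical(nrow(out), 1L)
  expect_equal(out$geo_mean_pPAS, 20)
  expect_equal(out$geo_mean_dPAS, 80)
  # drop dPAS below threshold
  asg2 <- asg[c(1:25, 26:44), ]
  expect_identical(nrow(apa_isoform_tail_comparison(asg2, lens[1:44],
                                                    catalog)), 0L)
})

test_that("CPM columns are conserved at one million", {
  counts <- matrix(c(10, 999990, 10, 990), ncol = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m <- cpm(counts)
  expect_equal(m["g1", "s1"], 10)
  expect_equal(m["g1", "s2"], 10000)
  expect_equal(unname(colSums(m)), c(1e6, 1e6))
  expect_error(cpm(matrix(0, 2, 1)), "zero total")
})

test_that("differential expression computes log2FC with pseudocount", {
  a <- matrix(rep(10, 3), nrow = 1)
  b <- matrix(c(40, 40.5, 39.5), nrow = 1)
  out <- differential_expression(a, b)
  expect_equal(out$log2FC, log2(41 / 11), tolerance = 1e-12)
  expect_equal(out$p,
               stats::t.test(c(40, 40.5, 39.5), c(10, 10, 10),
                             var.equal = TRUE)$p.value)
  # identical groups: no flag, p = 1 at zero variance
  same <- matrix(rep(5, 4), nrow = 1)
  out0 <- differential_expression(same, same)
  expect_equal(out0$log2FC, 0)
  expect_equal(out0$p, 1)
  expect_identical(as.character(out0$flag), "ns")
})

test_that("tail-length histogram normalizes and reports the exact median", {
  lens <- rep(c(18L, 36L), each = 50)
  h <- tail_length_histogram(lens)
  expect_equal(h$median, 27)
  expect_equal(sum(h$histogram$density), 1)
  expect_equal(h$histogram$count[h$histogram$length == 18], 50)
  single <- tail_length_histogram(rep(42L, 10))
  expect_equal(single$median, 42)
  expect_equal(single$histogram$density[single$histogram$length == 42], 1)
  # overflow pooling
  over <- tail_length_histogram(c(10L, 400L), max_len = 250L)
  expect_equal(over$histogram$count[over$histogram$length == 250], 1)
})

test_that("gene summary applies the 20-read gate and joins PDI calls", {
  rec <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), c(25, 10)),
    tail_seq = c(rep("AAAAT", 25), rep("AAAA", 10)))
  asg <- tibble::tibble(
    gene_id = rep("g1", 25), read_id = sprintf("r%d", 1:25),
    category = rep(c("PDI", "PIT"), c(10, 15)))
  out <- gene_summary(rec, asg)
  expect_identical(out$gene_id, "g1")
  expect_equal(out$prop_with_U, 1)
  expect_equal(out$pdi_proportion, 0.4)
  expect_equal(out$geo_mean_tail_length, 5)
})
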