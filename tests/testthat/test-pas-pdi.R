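test_that("read end position follows transcript orientation", {
  expect_identical(read_end_position(10, 110, "+"), 110L)
  expect_identical(read_end_position(10, 110, "-"), 10L)
  expect_identical(read_end_position(c(5, 5), c(50, 50), "+"), c(50L, 50L))
})

test_that("greedy PAS calling reproduces the worked pileup", {
  ends <- rep(c(100L, 103L, 130L, 145L), c(15L, 3L, 12L, 9L))
  got <- call_pas(ends)
  # 100 and 103 tie at window support 18; 100 wins on exact count; 145 is
  # within 20 nt of 130 and under-supported anyway
  expect_identical(got$position, c(100L, 130L))
  expect_identical(got$support, c(18L, 12L))
  expect_identical(nrow(call_pas(rep(200L, 9))), 0L)
  expect_identical(call_pas(rep(500L, 10))$position, 500L)
  expect_identical(nrow(call_pas(integer(0))), 0L)
})

test_that("greedy caller equals the per-round exhaustive oracle", {
  set.seed(99)
  for (rep_i in 1:150) {
    n_clusters <- sample(1:4, 1)
    centers <- sort(sample(seq(100, 2000, by = 1), n_clusters))
    ends <- unlist(lapply(centers, function(ce) {
      ce + sample(-8:8, sample(5:80, 1), replace = TRUE,
                  prob = dnorm(-8:8, sd = sample(c(1, 3), 1)))
    }))
    strand <- sample(c("+", "-"), 1)
    got <- call_pas(ends, strand = strand)
    expect_identical(got$position, oracle_call_pas(ends, strand = strand))
    # catalog invariants
    if (nrow(got) > 1) {
      expect_true(min(dist(got$position)) > 20)
    }
    expect_true(all(got$support >= 10))
  }
})

test_that("proximal/distal labels follow the transcription start side", {
  cat2 <- tibble::tibble(position = c(1000L, 1500L), support = c(20L, 30L))
  plus <- label_proximal_distal(cat2, "+")
  expect_identical(as.character(plus$label[plus$position == 1000]), "pPAS")
  expect_identical(as.character(plus$label[plus$position == 1500]), "dPAS")
  minus <- label_proximal_distal(cat2, "-")
  expect_identical(as.character(minus$label[minus$position == 1500]),
                   "pPAS")
  cat3 <- tibble::tibble(position = c(1L, 30L, 60L), support = rep(10L, 3))
  expect_true(all(label_proximal_distal(cat3, "+")$label == "other"))
})

test_that("read classification implements the PIT/PDI predicates", {
  catalog <- tibble::tibble(position = c(100L, 130L))
  got <- classify_reads(c("a", "b", "c", "d", "e"),
                        c(98L, 90L, 150L, 95L, 110L), catalog, "+")
  expect_identical(as.character(got$category),
                   c("PIT", "PDI", "UNASSIGNED", "PIT", "PDI"))
  expect_identical(got$matched_pas, c(100L, NA, NA, 100L, NA))
  # end exactly window nt from the site is a PIT (inclusive window)
  expect_identical(
    as.character(classify_reads("x", 125L, catalog, "+")$category), "PIT")
  # minus strand mirrors the upstream direction
  expect_identical(
    as.character(classify_reads("y", 140L, catalog, "-")$category), "PDI")
  expect_identical(
    as.character(classify_reads("z", 80L, catalog, "-")$category),
    "UNASSIGNED")
  # no catalog: everything unassigned
  none <- classify_reads("w", 100L, tibble::tibble(position = integer(0)),
                         "+")
  expect_identical(as.character(none$category), "UNASSIGNED")
})

test_that("PIT distance ties resolve to the 5'-most site", {
  catalog <- tibble::tibble(position = c(100L, 108L))
  got <- classify_reads("t", 104L, catalog, "+")
  expect_identical(got$matched_pas, 100L)
  got_minus <- classify_reads("t", 104L, catalog, "-")
  expect_identical(got_minus$matched_pas, 108L)
})

test_that("PDI end regions separate CDS from 3'-UTR ends", {
  catalog <- tibble::tibble(position = 1000L)
  got <- classify_reads(c("a", "b"), c(500L, 950L), catalog, "+",
                        cds_start = 1L, cds_end = 800L,
                        last_exon_start = 700L, last_exon_end = 1100L)
  expect_identical(as.character(got$end_region), c("CDS", "UTR3"))
})
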