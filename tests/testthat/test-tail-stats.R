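test_that("tail annotation counts bases and the non-A total", {
  rec <- annotate_tail("r1", "g1", "bc", 12L, c("AATGA", "", "TTTT"))
  expect_equal(rec$count_A, c(3L, 0L, 0L))
  expect_equal(rec$count_T, c(1L, 0L, 4L))
  expect_equal(rec$count_C, c(0L, 0L, 0L))
  expect_equal(rec$count_G, c(1L, 0L, 0L))
  expect_equal(rec$count_nonA, c(2L, 0L, 4L))
  expect_identical(rec$const1, rep("1", 3))
  expect_identical(rec$const0, rep("0", 3))
})

test_that("N bases stay in the sequence but out of every count", {
  rec <- annotate_tail("r", "g", "b", 10L, "AANTA")
  expect_equal(rec$count_A + rec$count_T + rec$count_C + rec$count_G, 4L)
  expect_equal(rec$count_nonA, 1L)
  expect_identical(rec$tail_seq, "AANTA")
})

test_that("longest runs and run groups follow the U/C/G partitions", {
  expect_identical(longest_run("AATTTAA", "T"), 3L)
  expect_identical(as.character(run_group("AATTTAA", "T")), "U2-5")
  expect_identical(longest_run("AAAA", "T"), 0L)
  expect_identical(as.character(run_group("AAAA", "T")), "none")
  expect_identical(longest_run("ATTTTTTA", "T"), 6L)
  expect_identical(as.character(run_group("ATTTTTTA", "T")), "U>=6")
  expect_identical(longest_run("AGGA", "G"), 2L)
  expect_identical(as.character(run_group("AGGA", "G")), "G2")
  expect_identical(as.character(run_group("ACCCA", "C")), "C>=3")
  expect_identical(as.character(run_group("ACA", "C")), "C1")
})

test_that("longest_run equals the exhaustive oracle on random tails", {
  set.seed(7)
  tails <- random_tails(2000, max_len = 120, a_bias = TRUE)
  for (b in c("T", "C", "G")) {
    expect_identical(longest_run(tails, b),
                     vapply(tails, oracle_longest_run, integer(1), base = b,
                            USE.NAMES = FALSE))
  }
})

test_that("3'-end placement takes precedence over internal", {
  expect_identical(as.character(residue_position_class("AAAT", "T")), "end3")
  expect_identical(as.character(residue_position_class("ATAA", "T")),
                   "internal")
  expect_identical(as.character(residue_position_class("TAAT", "T")), "end3")
  expect_identical(as.character(residue_position_class("AAAA", "T")), "none")
  # single-adapter reporting collapses end3 into internal
  expect_identical(
    as.character(residue_position_class("AAAT", "T",
                                        collapse_end3_to_internal = TRUE)),
    "internal")
})

test_that("N length locates the unique longest U run, NA on ties", {
  expect_identical(n_length("AAATTTA"), 3L)
  expect_identical(n_length("TTAAAA"), 0L)
  expect_identical(n_length("ATTAATTA"), NA_integer_)
  expect_error(n_length("AAAA"), "at least one U")
})

test_that("N length and run-group invariants hold on random tails", {
  set.seed(13)
  tails <- random_tails(3000, max_len = 80, a_bias = TRUE)
  prof <- tail_profile(tails)
  with_t <- prof$run_T > 0
  defined <- with_t & !is.na(prof$n_length_U)
  expect_true(all(prof$n_length_U[defined] + prof$run_T[defined] <=
                    prof$tail_length[defined]))
  # a defined N length points at an actual T run of the maximal length
  idx <- utils::head(which(defined), 200)
  for (i in idx) {
    run <- substr(tails[i], prof$n_length_U[i] + 1,
                  prof$n_length_U[i] + prof$run_T[i])
    expect_identical(run, strrep("T", prof$run_T[i]))
  }
  # run-group partition: counts over the four groups sum to all tails
  expect_identical(sum(table(prof$group_U)), length(tails))
  expect_true(all((prof$group_U == "none") == (prof$run_T == 0)))
  # exactly one position class per tail, end3 only with matching last base
  expect_true(all(!is.na(prof$pos_U)))
  last <- substr(tails, nchar(tails), nchar(tails))
  expect_true(all((prof$pos_U == "end3") == (last == "T")))
})
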