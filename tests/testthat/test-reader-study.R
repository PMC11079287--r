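test_that("revision directions are tallied per status change only", {
  truth <- toy_map(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  before <- toy_map(matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2), source = "reader")
  after <- toy_map(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), source = "reader")
  rev <- classify_revisions(before, after, truth)
  expect_equal(rev[["fn_to_tp"]], 1L) # missed cancer grid picked up
  expect_equal(rev[["fp_to_tn"]], 1L) # false alarm withdrawn
  expect_equal(rev[["tp_to_fn"]] + rev[["tn_to_fp"]], 0L)

  # unrevised maps produce no tallies at all
  expect_equal(sum(classify_revisions(before, before, truth)), 0L)
})

test_that("revision tallies equal the brute-force per-grid enumeration", {
  set.seed(71)
  for (rep in 1:8) {
    truth <- random_map(20, 20, 0.3)
    before <- random_map(20, 20, 0.4, source = "reader")
    after <- random_map(20, 20, 0.4, source = "reader")
    got <- classify_revisions(before, after, truth)
    want <- brute_revisions(as.vector(before$labels), as.vector(after$labels),
                            as.vector(truth$labels))
    expect_equal(got, want)
  }
})

test_that("after-condition confusion equals before shifted by the four tallies", {
  set.seed(72)
  truth <- random_map(30, 30, 0.25)
  ai <- random_map(30, 30, 0.3, source = "ai")
  prof <- reader_profile("R1", "junior")
  pair <- simulate_reader(truth, ai, prof)
  rev <- classify_revisions(pair$before, pair$after, truth)
  cb <- grid_confusion(pair$before, truth)
  ca <- grid_confusion(pair$after, truth)
  expect_equal(ca$tp, cb$tp + rev[["fn_to_tp"]] - rev[["tp_to_fn"]])
  expect_equal(ca$fn, cb$fn - rev[["fn_to_tp"]] + rev[["tp_to_fn"]])
  expect_equal(ca$tn, cb$tn + rev[["fp_to_tn"]] - rev[["tn_to_fp"]])
  expect_equal(ca$fp, cb$fp - rev[["fp_to_tn"]] + rev[["tn_to_fp"]])
})

test_that("McNemar test is two-sided, symmetric and sane at the extremes", {
  big <- mcnemar_test(122, 2)
  expect_lt(big$p_value, 1e-4)
  expect_equal(big$method_used, "chisq_cc")
  expect_lt(mcnemar_test(122, 2, method = "exact")$p_value, 1e-4)

  # symmetry in b and c
  expect_equal(mcnemar_test(15, 3)$p_value, mcnemar_test(3, 15)$p_value)
  expect_equal(mcnemar_test(80, 40)$p_value, mcnemar_test(40, 80)$p_value)

  # balanced discordance: exact two-sided p = 1 by binomial symmetry
  expect_equal(mcnemar_test(5, 5)$p_value, 1.0)

  deg <- mcnemar_test(0, 0)
  expect_equal(deg$p_value, 1.0)
  expect_true(deg$degenerate)

  # variant switch at b + c = 25
  expect_equal(mcnemar_test(12, 12)$method_used, "exact")
  expect_equal(mcnemar_test(13, 12)$method_used, "chisq_cc")
})

test_that("chi-square variant matches stats::mcnemar.test with correction", {
  for (bc in list(c(122, 2), c(40, 25), c(300, 150))) {
    ours <- mcnemar_test(bc[1], bc[2], method = "chisq")
    ref <- stats::mcnemar.test(matrix(c(5, bc[1], bc[2], 5), 2, 2),
                               correct = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value))
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("exact variant matches the binomial sign test", {
  for (bc in list(c(8, 2), c(5, 5), c(0, 7))) {
    ours <- mcnemar_test(bc[1], bc[2], method = "exact")
    ref <- stats::binom.test(bc[1], bc[1] + bc[2], 0.5)
    expect_equal(ours$p_value, ref$p.value)
  }
})

test_that("paired performance pools counts and flags incomplete pairing", {
  set.seed(73)
  truth <- list(s1 = random_map(8, 8, 0.3), s2 = random_map(8, 8, 0))
  mk_maps <- function() lapply(truth, function(t) random_map(8, 8, 0.3,
                                                             source = "reader"))
  shared_before <- mk_maps()
  shared_after <- mk_maps()
  readers <- list(
    list(reader_id = "A", before = shared_before, after = shared_after),
    list(reader_id = "B", before = shared_before, after = shared_after)
  )
  perf <- paired_performance(readers, truth)
  # two identical readers: pooled estimate equals each reader's own
  cc_a <- perf$per_reader$A$without_ai$grid
  pooled <- perf$pooled$without_ai$grid$counts
  expect_equal(pooled$tp, 2 * cc_a$tp)
  expect_equal(perf$pooled$without_ai$grid$sensitivity$estimate,
               cc_a$tp / (cc_a$tp + cc_a$fn))
  expect_equal(perf$summary$macro_sensitivity[1],
               perf$summary$sensitivity[1])

  broken <- list(list(reader_id = "C", before = shared_before["s1"],
                      after = shared_after))
  expect_error(paired_performance(broken, truth),
               class = "wsigrid_pairing_error")
})

test_that("a missed slide has zero correctly marked positive grids", {
  t1 <- matrix(FALSE, 5, 5); t1[1:2, 1:2] <- TRUE
  truth <- list(p1 = toy_map(t1), p2 = toy_map(t1), n1 = toy_map(matrix(FALSE, 5, 5)))
  ann <- list(
    p1 = toy_map({m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m}, source = "reader"),
    p2 = toy_map({m <- matrix(FALSE, 5, 5); m[5, 5] <- TRUE; m}, source = "reader"),
    n1 = toy_map(matrix(FALSE, 5, 5), source = "reader")
  )
  ms <- missed_slides(ann, truth, "R1")
  # p1: one of four positive grids marked -> not missed; p2: only a
  # false-alarm grid marked -> missed
  expect_equal(ms$missed_slide_ids, "p2")

  perfect <- missed_slides(truth, truth, "oracle")
  expect_equal(length(perfect$missed_slide_ids), 0L)
})

test_that("venn overlap counts match brute-force membership enumeration", {
  simple <- venn_overlap(list(a = c("s1", "s2"), b = c("s2", "s3")))
  expect_equal(unname(simple$intersections["a&b"]), 1L)
  expect_equal(simple$union_size, 3L)
  expect_equal(unname(simple$exclusive["a"]), 1L)
  expect_equal(sum(simple$exclusive), simple$union_size)

  set.seed(74)
  universe <- sprintf("w%02d", 1:26)
  sets <- lapply(1:5, function(i) sample(universe, sample(0:12, 1)))
  names(sets) <- paste0("obs", 1:5)
  venn <- venn_overlap(sets)
  # brute force every subset
  for (nm in names(venn$intersections)) {
    members <- strsplit(nm, "&", fixed = TRUE)[[1]]
    want <- Reduce(intersect, sets[members])
    expect_equal(unname(venn$intersections[nm]), length(want))
    excl <- setdiff(want, unlist(sets[setdiff(names(sets), members)]))
    expect_equal(unname(venn$exclusive[nm]), length(excl))
  }
  expect_equal(sum(venn$exclusive), venn$union_size)
  expect_equal(venn$union_size, length(unique(unlist(sets))))
})
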