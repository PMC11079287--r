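small_cfg <- function(seed = 101, ...) {
  cohort_config(n_slides = 40, slide_grids = c(16L, 24L),
                lesion_area_mm2 = c(0.5, 10), seed = seed, ...)
}

test_that("cohort generation is deterministic under the config seed", {
  a <- generate_cohort(small_cfg())
  b <- generate_cohort(small_cfg())
  expect_identical(lapply(a, function(r) r$truth$labels),
                   lapply(b, function(r) r$truth$labels))
  expect_identical(vapply(a, `[[`, character(1), "procedure"),
                   vapply(b, `[[`, character(1), "procedure"))
  # a different seed changes the draw
  c <- generate_cohort(small_cfg(seed = 102))
  expect_false(identical(lapply(a, function(r) r$truth$labels),
                         lapply(c, function(r) r$truth$labels)))
})

test_that("lesions are 4-connected with grid count matching the sampled area", {
  recs <- generate_cohort(small_cfg(seed = 103))
  pos <- Filter(function(r) any(r$truth$labels), recs)
  expect_gt(length(pos), 0)
  for (r in pos) {
    expect_true(is_4connected(r$truth$labels))
    expect_equal(r$cancer_area_mm2, r$n_positive_grids * 0.0625)
    expect_gte(r$cancer_area_mm2, 0.5 - 0.0625) # within one grid of minimum
  }
})

test_that("degenerate cohort configs behave as declared", {
  none <- generate_cohort(cohort_config(n_slides = 15, prevalence = 0,
                                        slide_grids = c(10L, 12L), seed = 104))
  expect_false(any(vapply(none, function(r) any(r$truth$labels), logical(1))))

  # fixed lesion area of 0.5 mm^2 -> exactly 8 positive fine grids
  fixed <- generate_cohort(cohort_config(n_slides = 20, prevalence = 1,
                                         slide_grids = c(10L, 12L),
                                         lesion_area_mm2 = c(0.5, 0.5),
                                         seed = 105))
  expect_true(all(vapply(fixed, `[[`, integer(1), "n_positive_grids") == 8L))

  # a lesion that cannot fit the slide is a config error
  expect_error(cohort_config(n_slides = 5, slide_grids = c(3L, 4L),
                             lesion_area_mm2 = c(349.25, 349.25)),
               class = "wsigrid_config_error")
})

test_that("oracle rates converge to the configured operating point", {
  set.seed(106)
  truth <- toy_map(matrix(runif(250000) < 0.3, 500, 500))
  pred <- simulate_oracle(truth, oracle_config(), scores = FALSE)
  emp_sens <- mean(pred$labels[truth$labels])
  emp_spec <- mean(!pred$labels[!truth$labels])
  expect_equal(emp_sens, 0.9025, tolerance = 0.01)
  expect_equal(emp_spec, 0.9660, tolerance = 0.005)
})

test_that("oracle honours degenerate operating points exactly", {
  set.seed(107)
  truth <- random_map(20, 20, 0.4)
  perfect <- simulate_oracle(truth, oracle_config(1, 1), scores = FALSE)
  expect_identical(perfect$labels, truth$labels)
  paranoid <- simulate_oracle(truth, oracle_config(1, 0), scores = FALSE)
  expect_true(all(paranoid$labels))
})

test_that("oracle scores are consistent with labels for ROC use", {
  set.seed(108)
  truth <- random_map(60, 60, 0.3)
  pred <- simulate_oracle(truth, oracle_config())
  expect_true(all(pred$scores[pred$labels] >= 0.5))
  expect_true(all(pred$scores[!pred$labels] <= 0.5))
  auc <- roc_auc(as.vector(pred$scores), as.vector(truth$labels))
  expect_gt(auc, 0.9) # near the configured operating point's power
})

test_that("spatially correlated errors keep marginal rates and clump", {
  set.seed(109)
  truth <- toy_map(matrix(runif(40000) < 0.5, 200, 200))
  pred <- simulate_oracle(truth, oracle_config(spatial_correlation = 4),
                          scores = FALSE)
  emp_sens <- mean(pred$labels[truth$labels])
  expect_equal(emp_sens, 0.9025, tolerance = 0.03)
  # clumped misses: mean 4-neighbour agreement among error grids exceeds
  # what independent errors would give (error rate ~0.1 -> neighbours of an
  # error are errors far more often than 10% of the time)
  miss <- truth$labels & !pred$labels
  idx <- which(miss, arr.ind = TRUE)
  idx <- idx[idx[, 1] < 200, , drop = FALSE]
  below_also_miss <- miss[cbind(idx[, 1] + 1L, idx[, 2])]
  expect_gt(mean(below_also_miss), 0.25)
})

test_that("reader simulation respects its closed-form revision structure", {
  set.seed(110)
  truth <- random_map(50, 50, 0.3)
  ai <- simulate_oracle(truth, oracle_config(), scores = FALSE)

  # zero revision probabilities: after identical to before
  frozen <- reader_profile("R0", "junior",
                           revision_probs = c(fn_to_tp = 0, tp_to_fn = 0,
                                              fp_to_tn = 0, tn_to_fp = 0))
  pair <- simulate_reader(truth, ai, frozen)
  expect_identical(pair$before$labels, pair$after$labels)

  # deterministic uptake: every miss the AI flagged is revised
  eager <- reader_profile("R1", "senior", sensitivity = 0.6,
                          revision_probs = c(fn_to_tp = 1, tp_to_fn = 0,
                                             fp_to_tn = 0, tn_to_fp = 0))
  pair2 <- simulate_reader(truth, ai, eager)
  missed_flagged <- truth$labels & !pair2$before$labels & ai$labels
  expect_true(all(pair2$after$labels[missed_flagged]))
  rev <- classify_revisions(pair2$before, pair2$after, truth)
  expect_equal(rev[["fn_to_tp"]], sum(missed_flagged))
  expect_equal(sum(rev) - rev[["fn_to_tp"]], 0L)
})

test_that("revision mass matches its analytic expectation", {
  # sens_after = sens_before + p_flip * P(before FN & AI TP) / P, so with
  # p_flip = 0.5, sensitivity 0.8, oracle sensitivity 0.9:
  # E(gain) = 0.5 * 0.2 * 0.9 = 0.09
  set.seed(111)
  truth <- toy_map(matrix(runif(90000) < 0.5, 300, 300))
  ai <- simulate_oracle(truth, oracle_config(0.9, 0.97), scores = FALSE)
  prof <- reader_profile("R2", "junior", sensitivity = 0.8,
                         revision_probs = c(fn_to_tp = 0.5, tp_to_fn = 0,
                                            fp_to_tn = 0, tn_to_fp = 0))
  pair <- simulate_reader(truth, ai, prof)
  sens_before <- mean(pair$before$labels[truth$labels])
  sens_after <- mean(pair$after$labels[truth$labels])
  expect_equal(sens_after - sens_before, 0.09, tolerance = 0.01)
})
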