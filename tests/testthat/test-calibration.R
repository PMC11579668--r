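test_that("the events measure is the identity of the common measure", {
  coh <- make_uniform_cohort(20, k = 3L)
  expect_equal(modeled_measure_rr(coh, 0.37, "events"), 0.37)
  res <- calibrate(calibration_problem(coh, 0.68, measure = "events"))
  expect_equal(res$rr_common, 0.68)
  expect_true(res$converged)
  expect_equal(nrow(res$iterations), 0)  # zero refinement steps
  expect_match(res$mode, "direct")
})

test_that("closed-form modeled measures match hand-derived values", {
  one <- make_uniform_cohort(15, k = 1L)
  expect_equal(modeled_measure_rr(one, 0.55, "patients"), 0.55)  # no
                                                                # clustering
  two <- make_uniform_cohort(15, k = 2L)
  expect_equal(modeled_measure_rr(two, 0.4, "patients"), 1 - 0.6^2)
  # patient-days: both events of each admission on one day
  adm <- make_admissions(10, los = 2L)
  ev <- tibble::tibble(admission_id = rep(1:10, each = 2), day = 0L,
                       category = "nonsevere_hypo")
  same_day <- cohort(adm, ev)
  expect_equal(modeled_measure_rr(same_day, 0.4, "patient_days"),
               1 - 0.6^2)
  expect_equal(modeled_measure_rr(two, 0.4, "patient_days"), 0.4)
})

test_that("calibration inverts the patients measure analytically", {
  two <- make_uniform_cohort(50, k = 2L)
  res <- calibrate(calibration_problem(two, 0.64, measure = "patients"))
  expect_true(res$converged)
  expect_lt(abs(res$rr_common - 0.4), 0.001)
  expect_lte(res$achieved_diff, 0.001)
  expect_gt(nrow(res$iterations), 0)
  # null effect maps to null effect
  null <- calibrate(calibration_problem(two, 1.0, measure = "patients"))
  expect_lt(abs(null$rr_common - 1.0), 0.001)
})

test_that("the modeled measure is strictly increasing and clustering pulls
           the calibrated rr below the published one", {
  set.seed(23)
  coh <- make_mixed_cohort(rpois(120, 0.4), 1 + rpois(120, 1.2))
  rrs <- seq(0.05, 0.95, by = 0.1)
  for (m in c("patients", "patient_days")) {
    vals <- vapply(rrs, modeled_measure_rr, numeric(1), cohort = coh,
                   measure = m)
    expect_true(all(diff(vals) > 0))
    res <- calibrate(calibration_problem(coh, 0.6, measure = m))
    expect_true(res$converged)
    expect_lt(res$rr_common, 0.6)  # some units hold >= 2 events
  }
})

test_that("non-convergence is reported, never silently answered", {
  two <- make_uniform_cohort(30, k = 2L)
  res <- calibrate(calibration_problem(two, 0.64, measure = "patients",
                                       tolerance = 1e-9, max_iter = 3))
  expect_false(res$converged)
  expect_match(res$reason, "max_iter")
  expect_equal(nrow(res$iterations), 3)
})

test_that("joint calibration is self-consistent at the returned pair", {
  set.seed(41)
  coh <- make_mixed_cohort(rbinom(150, 2, 0.35), rpois(150, 1.6))
  jc <- calibrate_joint(coh, published_rr_severe = 0.31,
                        published_rr_total = 0.64,
                        measure = "patient_days")
  expect_true(jc$converged)
  # recomputing both modeled measures reproduces both targets
  expect_lt(abs(modeled_measure_rr(coh, jc$rr_common_severe,
                                   "patient_days", "severe") - 0.31),
            0.001)
  expect_lt(abs(modeled_measure_rr(coh, jc$rr_common_nonsevere,
                                   "patient_days", "total",
                                   rr_severe = jc$rr_common_severe)
                - 0.64), 0.001)
  # null targets return the null pair
  null <- calibrate_joint(coh, 1.0, 1.0, measure = "patient_days")
  expect_lt(abs(null$rr_common_severe - 1), 0.001)
  expect_lt(abs(null$rr_common_nonsevere - 1), 0.001)
})

test_that("joint calibration degenerates to a single channel without
           severe events", {
  coh <- make_uniform_cohort(40, k = 2L)  # non-severe only
  jc <- calibrate_joint(coh, published_rr_severe = 0.31,
                        published_rr_total = 0.64, measure = "patients")
  expect_true(jc$converged)
  single <- calibrate(calibration_problem(coh, 0.64,
                                          measure = "patients"))
  expect_equal(jc$rr_common_nonsevere, single$rr_common)
})

test_that("infeasible joint targets produce an explicit report", {
  # all events severe: with the severe channel pinned at the severe
  # target, the total measure is already determined and cannot reach a
  # much larger target
  coh <- make_uniform_cohort(40, k = 2L, severe = TRUE)
  jc <- calibrate_joint(coh, published_rr_severe = 0.31,
                        published_rr_total = 0.95, measure = "patients")
  expect_false(jc$converged)
  expect_match(jc$reason, "infeasible")
})

test_that("applying calibrated rrs reproduces the published measure
           (round trip)", {
  set.seed(53)
  coh <- make_mixed_cohort(rbinom(400, 1, 0.2), 1 + rpois(400, 1.4))
  res <- calibrate(calibration_problem(coh, 0.7, measure = "patients"))
  bs <- bootstrap_prevention(coh, res$rr_common, res$rr_common,
                             target_filter = "all", n_boot = 400,
                             seed = 9)
  modeled <- bs$means[["patients_remaining"]] /
    bs$means[["patients_baseline"]]
  se <- stats::sd(bs$replicates$patients_remaining /
                  bs$replicates$patients_baseline) / sqrt(bs$n_boot)
  expect_lt(abs(modeled - 0.7), 0.001 + 3 * se)
})

test_that("calibration results serialize with their iteration trace", {
  two <- make_uniform_cohort(25, k = 2L)
  res <- calibrate(calibration_problem(two, 0.64, measure = "patients"))
  f <- tempfile(fileext = ".json")
  write_calibration_json(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$rr_common, res$rr_common)
  expect_equal(nrow(back$iterations), nrow(res$iterations))
  unlink(f)
})
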