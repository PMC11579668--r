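test_that("rr = 1 is the identity and rr = 0 prevents every eligible
           event", {
  coh <- make_uniform_cohort(50, k = 3L)
  same <- apply_intervention(coh, 1, 1, seed = 1)
  expect_equal(sum(same$events$prevented), 0)
  all_gone <- apply_intervention(coh, 0, 0, seed = 1)
  expect_equal(sum(all_gone$events$prevented), nrow(coh$events))
})

test_that("hyperglycemia and out-of-target events are never prevented", {
  adm <- make_admissions(3, los = 3L, obstetric = c(FALSE, TRUE, FALSE))
  ev <- tibble::tibble(admission_id = c(1L, 1L, 2L, 3L),
                       day = c(0L, 1L, 0L, 0L),
                       category = c("nonsevere_hypo", "hyper",
                                    "nonsevere_hypo", "severe_hypo"))
  coh <- cohort(adm, ev)
  out <- apply_intervention(coh, 0, 0, seed = 2)  # prevent-all boundary
  prevented <- out$events$prevented
  expect_false(any(prevented[out$events$category == "hyper"]))
  expect_false(any(prevented[out$events$admission_id == 2L]))  # obstetric
  expect_true(all(prevented[out$events$category != "hyper" &
                            out$events$admission_id != 2L]))
})

test_that("retained events stay within binomial bounds at rr = 0.85", {
  n <- 10000L
  coh <- make_uniform_cohort(n, k = 1L)
  out <- apply_intervention(coh, 0.85, 0.85, seed = 7)
  retained <- sum(!out$events$prevented)
  bounds <- qbinom(c(0.0005, 0.9995), n, 0.85)
  expect_gte(retained, bounds[1])
  expect_lte(retained, bounds[2])
})

test_that("relative risks outside [0, 1] are rejected", {
  coh <- make_uniform_cohort(5, k = 1L)
  expect_error(apply_intervention(coh, 1.2, 0.5), "rr_severe")
  expect_error(apply_intervention(coh, 0.5, -0.1), "rr_nonsevere")
})

test_that("reporting rule matches the dysglycemia criteria case by case", {
  rule <- reporting_rule()
  ev2h <- data.frame(day = c(0, 0, 1),
                     category = c("hyper", "hyper", "nonsevere_hypo"))
  expect_true(evaluate_reporting_rule(ev2h, 3, rule))   # 2 prior hyper
  ev1h <- data.frame(day = c(0, 1),
                     category = c("hyper", "nonsevere_hypo"))
  expect_false(evaluate_reporting_rule(ev1h, 2, rule))  # needs 2 or more
  ev1hypo <- data.frame(day = c(0, 1),
                        category = c("severe_hypo", "nonsevere_hypo"))
  expect_true(evaluate_reporting_rule(ev1hypo, 2, rule))  # 1 prior hypo
  expect_false(evaluate_reporting_rule(ev1hypo, 1, rule)) # empty history
  # events outside the one-day window do not count
  ev_far <- data.frame(day = c(0, 3),
                       category = c("severe_hypo", "nonsevere_hypo"))
  expect_false(evaluate_reporting_rule(ev_far, 2, rule))
})

test_that("events in admissions never meeting the rule are untouched", {
  # admission 1 never meets criteria (single hypo event, no history);
  # admission 2 meets it from its second event onward
  adm <- make_admissions(2, los = 3L)
  ev <- tibble::tibble(admission_id = c(1L, 2L, 2L, 2L),
                       day = c(0L, 0L, 0L, 1L),
                       category = c("nonsevere_hypo", "nonsevere_hypo",
                                    "nonsevere_hypo", "nonsevere_hypo"))
  coh <- cohort(adm, ev)
  out <- apply_intervention(coh, 0, 0, rule = reporting_rule(), seed = 3)
  p <- out$events$prevented
  expect_false(p[1])              # no history: shielded from prevention
  expect_false(p[2])              # first event of admission 2
  expect_true(all(p[3:4]))        # history contains a hypo event
})

test_that("bootstrap with rr = 1 returns exactly zero reductions", {
  coh <- make_uniform_cohort(40, k = 2L)
  bs <- bootstrap_prevention(coh, 1, 1, n_boot = 1, seed = 1)
  expect_equal(unname(bs$means["events_prevented_severe"]), 0)
  expect_equal(unname(bs$means["events_prevented_nonsevere"]), 0)
  expect_equal(unname(bs$means["patients_fully_prevented"]), 0)
  expect_equal(unname(bs$means["hac_reduction"]), 0)
})

test_that("single-event admissions are fully prevented at rate 1 - rr", {
  r <- 0.7
  coh <- make_uniform_cohort(400, k = 1L)
  bs <- bootstrap_prevention(coh, r, r, n_boot = 400, seed = 11)
  frac <- bs$means[["patients_fully_prevented"]] /
    bs$means[["patients_baseline"]]
  se <- stats::sd(bs$replicates$patients_fully_prevented /
                  bs$replicates$patients_baseline) / sqrt(bs$n_boot)
  expect_lt(abs(frac - (1 - r)), 3 * se + 0.005)
})

test_that("conservation holds in every bootstrap replicate", {
  cfg <- cohort_config(n_admissions = 1500, p_affected = 0.05, seed = 13)
  coh <- generate_cohort(cfg)
  bs <- bootstrap_prevention(coh, 0.5, 0.8, n_boot = 50, seed = 4)
  r <- bs$replicates
  expect_equal(r$events_prevented_severe + r$events_prevented_nonsevere +
                 (r$events_baseline - r$events_prevented_severe -
                    r$events_prevented_nonsevere),
               r$events_baseline)
  expect_equal(r$patients_fully_prevented + r$patients_remaining,
               r$patients_baseline)
  expect_true(all(r$patient_days_remaining <= r$patient_days_baseline))
  expect_equal(r$hac_reduction,
               bs$hac_fraction * r$patients_fully_prevented)
})

test_that("lowering either rr never decreases prevention under shared
           randomness", {
  cfg <- cohort_config(n_admissions = 2000, p_affected = 0.08,
                       severe_share = 0.3, seed = 17)
  coh <- generate_cohort(cfg)
  metrics <- c("events_prevented_severe", "events_prevented_nonsevere",
               "patients_fully_prevented", "hac_reduction")
  run <- function(rs, rn)
    bootstrap_prevention(coh, rs, rn, n_boot = 30, seed = 77)$means[metrics]
  base <- run(0.82, 0.82)
  stronger <- run(0.70, 0.70)
  expect_true(all(stronger >= base))
  sev_only <- run(0.70, 0.82)
  expect_true(all(sev_only >= base))
})

test_that("expected fully-prevented patients match the product closed
           form", {
  set.seed(31)
  s <- rbinom(500, 2, 0.4); ns <- rbinom(500, 3, 0.6)
  keep <- (s + ns) > 0
  coh <- make_mixed_cohort(s[keep], ns[keep])
  rr_s <- 0.5; rr_ns <- 0.8
  closed <- sum((1 - rr_s)^s[keep] * (1 - rr_ns)^ns[keep])
  bs <- bootstrap_prevention(coh, rr_s, rr_ns, n_boot = 300, seed = 5)
  se <- stats::sd(bs$replicates$patients_fully_prevented) /
    sqrt(bs$n_boot)
  expect_lt(abs(bs$means[["patients_fully_prevented"]] - closed), 3 * se)
})

test_that("intervention specs validate elicited ordering and scenarios", {
  ok <- intervention_spec("x", published_effect = list(
    outcome_measure = "events", rr_total_hypo = 0.7))
  expect_s3_class(ok, "intervention_spec")
  expect_error(intervention_spec("x", published_effect = list(
    outcome_measure = "events", rr_total_hypo = 1.3)), "\\(0, 1\\]")
  expect_error(intervention_spec("x",
    published_effect = list(outcome_measure = "events",
                            rr_total_hypo = 0.7),
    elicited_rrs = list(realistic = list(total_hypo = 0.8),
                        optimistic = list(total_hypo = 0.9),   # > realistic
                        pessimistic = list(total_hypo = 0.95))),
    "optimistic")
  coh <- make_uniform_cohort(10, k = 1L)
  gmt <- read_intervention_spec(system.file("extdata",
                                            "gmt_pharmacist.yaml",
                                            package = "lleesim"))
  expect_error(bootstrap_run(coh, gmt, "realistic"), "scenario")
})

test_that("missing severe relative risk inherits the total effect", {
  spec <- read_intervention_spec(system.file("extdata",
                                             "root_cause_survey.yaml",
                                             package = "lleesim"))
  coh <- make_uniform_cohort(60, k = 2L)
  bs <- bootstrap_run(coh, spec, "published", n_boot = 5, seed = 2)
  expect_equal(bs$rr_severe, bs$rr_nonsevere)
  expect_equal(bs$rr_nonsevere, 0.68)  # events measure: direct application
})
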