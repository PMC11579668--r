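test_that("penalty savings are exact multiples of the penalty", {
  expect_equal(penalty_savings(0), 0)
  expect_equal(penalty_savings(7), 7924)
  expect_equal(penalty_savings(10), 11320)
  expect_equal(penalty_savings(11), 12452)
  expect_error(penalty_savings(-1), ">= 0")
})

test_that("bed-day savings follow the 3-days-per-admission rule", {
  expect_equal(bed_day_savings(49), list(bed_days = 147, aud = 213150))
  expect_equal(bed_day_savings(32), list(bed_days = 96, aud = 139200))
  expect_equal(bed_day_savings(67), list(bed_days = 201, aud = 291450))
  expect_equal(bed_day_savings(0), list(bed_days = 0, aud = 0))
})

test_that("the derived bed-day cost exposes the price-weight product", {
  expect_equal(derive_bed_day_cost(), 0.2641 * 5597)  # 1478.17, not the
                                                      # adopted 1450
  expect_equal(derive_bed_day_cost(0, 5597), 0)
  expect_equal(derive_bed_day_cost(1, 5597), 5597)
})

test_that("nursing balance nets saved minus spent time to the minute", {
  # 12 severe * 25 min + 288 non-severe * 5 min = 29 h saved; 25 h spent
  expect_equal(nursing_time_balance(12, 288, 1500), 4)
  # 19 h saved against 25 h spent: 6 additional hours required
  expect_equal(nursing_time_balance(12, 168, 1500), -6)
  expect_equal(nursing_time_balance(0, 0, 0), 0)
  expect_equal(nursing_time_balance(1, 1, 1), (25 + 5 - 1) / 60)
})

test_that("staff hours truncate to whole hours and cost only funded
           lines", {
  vgms <- resource_profile(data.frame(
    role = c("endocrinology registrar", "CDE nurse", "CDE pharmacist"),
    fte = 0.2, annual_salary = c(120000, 100000, 110000), funded = TRUE))
  sh <- staff_hours_and_cost(vgms)
  expect_equal(sh$annual_hours, 1185)   # 3 * 0.2 * 38 * 52 = 1185.6
  expect_equal(sh$aud, 0.2 * 330000)
  full <- resource_profile(data.frame(role = "x", fte = 1,
                                      annual_salary = 9e4, funded = TRUE))
  expect_equal(staff_hours_and_cost(full)$annual_hours, 1976)  # 38 * 52
  empty <- staff_hours_and_cost(resource_profile())
  expect_equal(empty$annual_hours, 0)
  expect_equal(empty$aud, 0)
  unfunded <- resource_profile(data.frame(role = "nurse", fte = 0.5,
                                          annual_salary = 1e5,
                                          funded = FALSE))
  su <- staff_hours_and_cost(unfunded)
  expect_equal(su$aud, 0)
  expect_equal(su$unfunded_hours, 988)
})

test_that("per-cycle resource components sum to the cycle total", {
  prof <- resource_profile(once_off_hours = 88,
                           per_cycle_components = c(nursing = 25,
                                                    implementation = 19))
  expect_equal(prof$per_cycle_hours, 44)
})

test_that("assembled tables satisfy the exact-cost identities", {
  coh <- make_uniform_cohort(120, k = 2L)
  mk <- function(rr) bootstrap_prevention(coh, rr, rr, n_boot = 40,
                                          seed = 21)
  tabs <- list(realistic = mk(0.85), optimistic = mk(0.70),
               pessimistic = mk(0.95))
  ct <- assemble_cost_table(tabs, surveys_completed = 100)
  df <- as.data.frame(ct)
  row <- function(q) df[df$quantity == q, c("realistic", "optimistic",
                                            "pessimistic")]
  # dollar cells are quantity x unit cost exactly
  expect_equal(unlist(row("penalty_saving_aud")),
               unlist(row("hac_reduction")) * 1132)
  expect_equal(unlist(row("bed_day_saving_aud")),
               unlist(row("bed_days_avoided")) * 1450)
  expect_equal(unlist(row("bed_days_avoided")),
               unlist(row("patients_fully_prevented")) * 3)
  # penalty and bed-day divisibility
  expect_true(all(unlist(row("penalty_saving_aud")) %% 1132 == 0))
  expect_true(all(unlist(row("bed_days_avoided")) %% 3 == 0))
})

test_that("all-zero reductions give an all-zero table except fixed staff
           lines", {
  coh <- make_uniform_cohort(30, k = 1L)
  none <- bootstrap_prevention(coh, 1, 1, n_boot = 1, seed = 1)
  prof <- resource_profile(data.frame(role = "pharmacist", fte = 2,
                                      annual_salary = 105000,
                                      funded = TRUE))
  ct <- assemble_cost_table(list(realistic = none), profile = prof)
  expect_true(all(as.data.frame(ct)$realistic == 0))
  staff <- attr(ct, "staff")
  expect_equal(staff$staff_cost_aud, 210000)
  expect_gt(staff$annual_staff_hours, 0)
})

test_that("doubling reductions doubles every variable dollar value", {
  fake <- function(mult) {
    m <- c(events_prevented_severe = 6 * mult,
           events_prevented_nonsevere = 40 * mult,
           patients_fully_prevented = 10 * mult,
           patients_remaining = 100, patient_days_remaining = 100,
           patient_days_baseline = 140, patients_baseline = 110,
           events_baseline = 160, hac_reduction = 4 * mult)
    structure(list(means = m, n_boot = 1, hac_fraction = 0.24,
                   replicates = tibble::as_tibble(as.list(m))),
              class = "bootstrap_summary")
  }
  t1 <- as.data.frame(assemble_cost_table(list(realistic = fake(1))))
  t2 <- as.data.frame(assemble_cost_table(list(realistic = fake(2))))
  vars <- c("penalty_saving_aud", "bed_day_saving_aud",
            "bed_days_avoided", "net_nursing_hours")
  for (v in vars)
    expect_equal(t2$realistic[t2$quantity == v],
                 2 * t1$realistic[t1$quantity == v])
})

test_that("missing scenarios are named in the error", {
  expect_error(assemble_cost_table(list(realistic = "not a summary")),
               "realistic")
  expect_error(assemble_cost_table(list()), "non-empty")
})

test_that("cost parameters load from the shipped YAML", {
  p <- read_cost_params(system.file("extdata", "cost_params.yaml",
                                    package = "lleesim"))
  expect_equal(p$penalty_per_hac, 1132)
  expect_equal(p$bed_day_cost, 1450)
  expect_equal(p$fte_hours_per_week, 38)
})
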