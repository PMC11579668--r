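#' Target-population filters
#'
#' Predicates over the admissions table selecting the population an
#' intervention can act on.  Hospital-wide interventions (root cause
#' survey, virtual glycemic management service) target adult non-obstetric
#' admissions; the peri-operative glycemic management team targets adult
#' non-obstetric surgical admissions including ICU stays.
#'
#' @param admissions admissions tibble of an `llee_cohort`.
#' @return logical vector, one element per admission.
#' @export
filter_adult_nonobstetric <- function(admissions) {
  admissions$adult & !admissions$obstetric
}

#' @rdname filter_adult_nonobstetric
#' @export
filter_surgical_incl_icu <- function(admissions) {
  admissions$adult & !admissions$obstetric &
    (admissions$surgical | admissions$icu)
}

resolve_target_filter <- function(target) {
  if (is.null(target)) return(filter_adult_nonobstetric)
  if (is.function(target)) return(target)
  switch(as.character(target),
         adult_nonobstetric = filter_adult_nonobstetric,
         surgical_incl_icu = filter_surgical_incl_icu,
         all = function(adm) rep(TRUE, nrow(adm)),
         stop("unknown target filter: ", target))
}

#' Dysglycemia reporting rule
#'
#' Defines which events sit inside an intervention's reach when the
#' service only reviews patients flagged by recent dysglycemia.  The base
#' case: a patient enters the daily report if they had two or more
#' hyperglycemia events (> 15.0 mmol/L) or one or more hypoglycemia events
#' (< 4.0 mmol/L) in the previous 24 hours.  The 24-hour window is
#' approximated by one model day: history events with
#' `day >= candidate_day - window_days` that occur before the candidate in
#' the admission's day-ordered event list.
#'
#' @param min_hyper,min_hypo event-count thresholds.
#' @param window_days look-back window in whole model days.
#' @return a `reporting_rule` object.
#' @export
reporting_rule <- function(min_hyper = 2L, min_hypo = 1L,
                           window_days = 1L) {
  stopifnot(min_hyper >= 0, min_hypo >= 0, window_days >= 0)
  structure(list(min_hyper = as.integer(min_hyper),
                 min_hypo = as.integer(min_hypo),
                 window_days = as.integer(window_days)),
            class = "reporting_rule")
}

#' Evaluate a reporting rule for one candidate event
#'
#' Returns `TRUE` if the admission's event history in the rule's window
#' before the candidate event satisfies the dysglycemia criteria.  History
#' is the *pre-intervention* record: events already marked prevented still
#' count toward the criteria.
#'
#' @param admission_events events of a single admission, ordered by day
#'   (ties keep their recorded order), with columns `day` and `category`.
#' @param event_index row index of the candidate event.
#' @param rule a [reporting_rule()].
#' @return logical scalar.
#' @examples
#' ev <- data.frame(day = c(0, 0, 1),
#'                  category = c("hyper", "hyper", "nonsevere_hypo"))
#' evaluate_reporting_rule(ev, 3, reporting_rule())  # TRUE: 2 prior hyper
#' @export
evaluate_reporting_rule <- function(admission_events, event_index, rule) {
  stopifnot(inherits(rule, "reporting_rule"),
            event_index >= 1, event_index <= nrow(admission_events))
  if (event_index == 1L) return(FALSE)
  hist_idx <- seq_len(event_index - 1L)
  day0 <- admission_events$day[event_index]
  in_window <- admission_events$day[hist_idx] >= day0 - rule$window_days
  cats <- admission_events$category[hist_idx][in_window]
  sum(cats == "hyper") >= rule$min_hyper ||
    sum(cats != "hyper") >= rule$min_hypo
}

# per-event eligibility flags under a reporting rule, for all events of
# admissions holding at least one hypoglycemia event
reporting_eligibility <- function(events, rule) {
  if (is.null(rule)) return(rep(TRUE, nrow(events)))
  out <- logical(nrow(events))
  idx_by_adm <- split(seq_len(nrow(events)), events$admission_id)
  for (idx in idx_by_adm) {
    sub <- events[idx, c("day", "category")]
    if (!any(sub$category != "hyper")) next
    for (j in seq_along(idx))
      out[idx[j]] <- evaluate_reporting_rule(sub, j, rule)
  }
  out
}

check_rr <- function(rr, name) {
  if (!is.numeric(rr) || length(rr) != 1L || is.na(rr) || rr < 0 || rr > 1)
    stop("parameter error: `", name, "` must be a relative risk in [0, 1] ",
         "(0 is the prevent-all boundary)", call. = FALSE)
  invisible(rr)
}

# Precompute the event-level arrays the prevention and bootstrap engines
# operate on.  Only hypoglycemia events can be prevented; hyperglycemia
# events enter through the reporting rule only.
prep_prevention <- function(cohort, target_filter = NULL,
                            reporting_rule = NULL) {
  adm <- cohort$admissions
  ev <- cohort$events
  filter_fn <- resolve_target_filter(target_filter)
  adm_elig <- filter_fn(adm)

  rule_ok <- reporting_eligibility(ev, reporting_rule)
  is_hypo <- ev$category != "hyper"
  hypo <- ev[is_hypo, ]
  hypo_rule_ok <- rule_ok[is_hypo]
  adm_row <- match(hypo$admission_id, adm$admission_id)

  aff_rows <- sort(unique(adm_row))          # affected admissions
  A <- length(aff_rows)
  ev_adm <- match(adm_row, aff_rows)          # 1..A per hypo event
  ord <- order(ev_adm)                        # group events by admission
  ev_adm <- ev_adm[ord]
  severe <- (hypo$category == "severe_hypo")[ord]
  day <- hypo$day[ord]
  elig <- (adm_elig[adm_row] & hypo_rule_ok)[ord]

  k <- tabulate(ev_adm, nbins = A)
  offset <- c(0L, cumsum(k))[seq_len(A)]
  # baseline per-admission summaries
  s_base <- tabulate(ev_adm[severe], nbins = A)
  ns_base <- k - s_base
  max_day <- max(c(day, 0L)) + 1L
  d_base <- tabulate(ev_adm[!duplicated(ev_adm * max_day + day)], nbins = A)

  list(n_adm = nrow(adm), aff_rows = aff_rows, A = A,
       ev_adm = ev_adm, severe = severe, day = day, elig = elig,
       k = k, offset = offset, s_base = s_base, ns_base = ns_base,
       d_base = d_base, max_day = max_day)
}

#' Apply an intervention to a cohort event-by-event
#'
#' Implements the stochastic prevention rule: for every hypoglycemia event
#' of an admission in the target population (and, if a reporting rule is
#' supplied, passing that rule), a uniform random number is drawn and the
#' event is marked prevented when the draw exceeds the relative risk of
#' the event's severity channel.  Hyperglycemia events are never
#' prevented; events outside the target population are untouched.
#'
#' @param cohort an `llee_cohort`.
#' @param rr_severe,rr_nonsevere event-level relative risks in `[0, 1]`
#'   (1 = no effect; 0 = prevent every eligible event).
#' @param target_filter `NULL` (adult non-obstetric), a filter name
#'   (`"adult_nonobstetric"`, `"surgical_incl_icu"`, `"all"`), or a
#'   predicate function over the admissions table.
#' @param rule optional [reporting_rule()] restricting which events the
#'   intervention can reach.
#' @param seed optional integer seed for the prevention draws.
#' @return the cohort with updated `prevented` flags on its events.
#' @export
apply_intervention <- function(cohort, rr_severe, rr_nonsevere,
                               target_filter = NULL, rule = NULL,
                               seed = NULL) {
  stopifnot(inherits(cohort, "llee_cohort"))
  check_rr(rr_severe, "rr_severe")
  check_rr(rr_nonsevere, "rr_nonsevere")
  if (!is.null(seed)) set.seed(seed)

  adm <- cohort$admissions
  ev <- cohort$events
  filter_fn <- resolve_target_filter(target_filter)
  adm_elig <- filter_fn(adm)
  rule_ok <- reporting_eligibility(ev, rule)
  is_hypo <- ev$category != "hyper"
  elig <- is_hypo & adm_elig[match(ev$admission_id, adm$admission_id)] &
    rule_ok
  rr <- ifelse(ev$category == "severe_hypo", rr_severe, rr_nonsevere)
  u <- stats::runif(nrow(ev))
  ev$prevented <- elig & (u > rr)
  cohort(adm, ev, config = attr(cohort, "config"))
}

#' Bootstrap the intervention effect on a cohort
#'
#' Resamples admissions (with their event lists) with replacement,
#' applies the stochastic prevention rule independently in each replicate,
#' and summarizes the prevented/remaining outcomes.  Admission-level
#' resampling preserves the within-patient clustering of events.  Coded
#' HAC reductions are computed in each replicate as `hac_fraction` times
#' the reduction in patients with at least one hypoglycemia event.
#'
#' @inheritParams apply_intervention
#' @param n_boot number of bootstrap replicates (study default 5,000).
#' @param seed integer seed.
#' @param hac_fraction coded-HAC share of affected admissions used for the
#'   HAC-reduction consequence (0.240 hospital-wide, 0.255 surgical).
#' @return a `bootstrap_summary`: list with `n_boot`, `replicates`
#'   (per-replicate tibble), `means`, `ci_lower`/`ci_upper` (2.5/97.5
#'   percentiles), and average baseline / remaining joint histograms over
#'   (severe, non-severe) event counts per affected admission.
#' @export
bootstrap_prevention <- function(cohort, rr_severe, rr_nonsevere,
                                 target_filter = NULL, rule = NULL,
                                 n_boot = 5000L, seed = 1L,
                                 hac_fraction = 0.240) {
  stopifnot(inherits(cohort, "llee_cohort"), n_boot >= 1)
  check_rr(rr_severe, "rr_severe")
  check_rr(rr_nonsevere, "rr_nonsevere")
  if (nrow(cohort$admissions) == 0L) stop("empty cohort")
  p <- prep_prevention(cohort, target_filter, rule)
  if (p$A == 0L) stop("cohort has no admissions with hypoglycemia events")
  set.seed(seed)

  smax <- max(p$s_base); nsmax <- max(p$ns_base)
  hist_base <- matrix(0, smax + 1L, nsmax + 1L,
                      dimnames = list(severe = 0:smax,
                                      nonsevere = 0:nsmax))
  hist_rem <- hist_base
  metrics <- c("events_prevented_severe", "events_prevented_nonsevere",
               "patients_fully_prevented", "patients_remaining",
               "patient_days_remaining", "patient_days_baseline",
               "patients_baseline", "events_baseline", "hac_reduction")
  out <- matrix(NA_real_, n_boot, length(metrics),
                dimnames = list(NULL, metrics))

  for (r in seq_len(n_boot)) {
    counts <- tabulate(sample.int(p$n_adm, p$n_adm, replace = TRUE),
                       nbins = p$n_adm)
    m <- counts[p$aff_rows]
    pos <- which(m > 0L); mm <- m[pos]
    copy_adm <- rep(pos, mm)
    C <- length(copy_adm)
    kk <- p$k[copy_adm]
    ev_idx <- sequence(kk) + rep(p$offset[copy_adm], kk)
    copy_id <- rep(seq_len(C), kk)
    sev_e <- p$severe[ev_idx]
    rr_e <- ifelse(sev_e, rr_severe, rr_nonsevere)
    prevented <- p$elig[ev_idx] & stats::runif(length(ev_idx)) > rr_e
    remaining <- !prevented

    rem_per_copy <- tabulate(copy_id[remaining], nbins = C)
    sev_rem <- tabulate(copy_id[remaining & sev_e], nbins = C)
    ns_rem <- rem_per_copy - sev_rem
    fully <- sum(rem_per_copy == 0L)
    day_key <- (copy_id - 1) * p$max_day + p$day[ev_idx]
    days_rem <- length(unique(day_key[remaining]))

    out[r, ] <- c(sum(prevented & sev_e), sum(prevented & !sev_e),
                  fully, C - fully, days_rem, sum(mm * p$d_base[pos]),
                  C, length(ev_idx), hac_fraction * fully)

    hb <- table(factor(p$s_base[copy_adm], levels = 0:smax),
                factor(p$ns_base[copy_adm], levels = 0:nsmax))
    hr <- table(factor(pmin(sev_rem, smax), levels = 0:smax),
                factor(pmin(ns_rem, nsmax), levels = 0:nsmax))
    hist_base <- hist_base + hb
    hist_rem <- hist_rem + hr
  }

  reps <- tibble::as_tibble(as.data.frame(out))
  structure(list(
    n_boot = n_boot,
    rr_severe = rr_severe, rr_nonsevere = rr_nonsevere,
    hac_fraction = hac_fraction,
    replicates = reps,
    means = colMeans(out),
    ci_lower = apply(out, 2, stats::quantile, probs = 0.025),
    ci_upper = apply(out, 2, stats::quantile, probs = 0.975),
    hist_baseline = hist_base / n_boot,
    hist_remaining = hist_rem / n_boot), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("<bootstrap_summary>", x$n_boot, "replicates\n")
  cat(sprintf("  rr_severe = %.4f, rr_nonsevere = %.4f\n",
              x$rr_severe, x$rr_nonsevere))
  m <- x$means
  cat(sprintf("  events prevented: %.1f severe, %.1f non-severe\n",
              m["events_prevented_severe"],
              m["events_prevented_nonsevere"]))
  cat(sprintf("  patients fully prevented: %.1f of %.1f\n",
              m["patients_fully_prevented"], m["patients_baseline"]))
  cat(sprintf("  coded HAC reduction: %.1f\n", m["hac_reduction"]))
  invisible(x)
}

#' Intervention specification
#'
#' Bundles everything needed to evaluate one service intervention: the
#' target population, the published effect (relative risk plus the outcome
#' measure it was reported on), the three-point elicited relative risks,
#' an optional dysglycemia reporting rule, the coded-HAC fraction for its
#' cohort, and its resource profile.
#'
#' @param name intervention label.
#' @param target target filter name (see [filter_adult_nonobstetric()]).
#' @param published_effect list with `outcome_measure` (one of `"events"`,
#'   `"patient_days"`, `"patients"`), `rr_total_hypo`, and optionally
#'   `rr_severe_hypo`.  When the severe relative risk is absent the severe
#'   channel inherits the total-hypoglycemia effect.
#' @param elicited_rrs optional list of scenarios `realistic`,
#'   `optimistic`, `pessimistic`, each a list with `total_hypo` and
#'   optionally `severe_hypo`; reported on the same outcome measure as the
#'   published effect.  Must satisfy optimistic <= realistic <=
#'   pessimistic per channel (a smaller relative risk is a larger effect).
#' @param reporting_criteria optional [reporting_rule()] or a list of its
#'   arguments.
#' @param hac_fraction coded-HAC share for this intervention's cohort.
#' @param resources optional [resource_profile()] or a list of its
#'   arguments.
#' @return an `intervention_spec` object.
#' @export
intervention_spec <- function(name, target = "adult_nonobstetric",
                              published_effect,
                              elicited_rrs = NULL,
                              reporting_criteria = NULL,
                              hac_fraction = 0.240,
                              resources = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  pe <- published_effect
  if (is.null(pe$outcome_measure) ||
      !pe$outcome_measure %in% c("events", "patient_days", "patients"))
    stop("published_effect$outcome_measure must be one of ",
         "'events', 'patient_days', 'patients'")
  check_rr_open <- function(rr, what) {
    if (!is.numeric(rr) || length(rr) != 1L || rr <= 0 || rr > 1)
      stop("parameter error: ", what, " must be in (0, 1]", call. = FALSE)
  }
  check_rr_open(pe$rr_total_hypo, "published rr_total_hypo")
  if (!is.null(pe$rr_severe_hypo))
    check_rr_open(pe$rr_severe_hypo, "published rr_severe_hypo")
  if (!is.null(elicited_rrs)) {
    need <- c("realistic", "optimistic", "pessimistic")
    if (!all(need %in% names(elicited_rrs)))
      stop("elicited_rrs must name scenarios: ",
           paste(need, collapse = ", "))
    for (ch in c("total_hypo", "severe_hypo")) {
      vals <- vapply(elicited_rrs[need],
                     function(s) s[[ch]] %||% NA_real_, numeric(1))
      if (all(is.na(vals))) next
      if (anyNA(vals))
        stop("elicited ", ch, " must be given for all scenarios or none")
      for (v in vals) check_rr_open(v, paste("elicited", ch))
      if (!(vals["optimistic"] <= vals["realistic"] &&
            vals["realistic"] <= vals["pessimistic"]))
        stop("elicited ", ch, " must satisfy optimistic <= realistic ",
             "<= pessimistic")
    }
  }
  if (!is.null(reporting_criteria) &&
      !inherits(reporting_criteria, "reporting_rule"))
    reporting_criteria <- do.call(reporting_rule, reporting_criteria)
  if (!is.null(resources) && !inherits(resources, "resource_profile"))
    resources <- do.call(resource_profile, resources)
  structure(list(name = name, target = target,
                 published_effect = pe, elicited_rrs = elicited_rrs,
                 reporting_criteria = reporting_criteria,
                 hac_fraction = hac_fraction, resources = resources),
            class = "intervention_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an intervention specification from YAML
#'
#' @param path YAML file; fields mirror the arguments of
#'   [intervention_spec()].  Three fixtures ship with the package under
#'   `inst/extdata/`: `root_cause_survey.yaml`, `vgms.yaml`,
#'   `gmt_pharmacist.yaml`.
#' @return an `intervention_spec`.
#' @examples
#' path <- system.file("extdata", "vgms.yaml", package = "lleesim")
#' spec <- read_intervention_spec(path)
#' @export
read_intervention_spec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(intervention_spec,
          y[intersect(names(y), names(formals(intervention_spec)))])
}

# scenario RRs on the spec's published outcome measure
scenario_rrs <- function(spec, scenario) {
  if (scenario == "published") {
    pe <- spec$published_effect
    list(total = pe$rr_total_hypo,
         severe = pe$rr_severe_hypo %||% pe$rr_total_hypo,
         severe_given = !is.null(pe$rr_severe_hypo))
  } else {
    if (is.null(spec$elicited_rrs) ||
        is.null(spec$elicited_rrs[[scenario]]))
      stop("scenario '", scenario, "' not available for intervention '",
           spec$name, "'")
    s <- spec$elicited_rrs[[scenario]]
    list(total = s$total_hypo,
         severe = s$severe_hypo %||% s$total_hypo,
         severe_given = !is.null(s$severe_hypo))
  }
}

#' Run one bootstrap scenario for an intervention
#'
#' Resolves the scenario's relative risks on the intervention's published
#' outcome measure, calibrates them onto the common event-level measure
#' when that measure is not already `"events"` (closed form), and runs
#' [bootstrap_prevention()].
#'
#' @param cohort an `llee_cohort`.
#' @param spec an [intervention_spec()].
#' @param scenario one of `"published"`, `"realistic"`, `"optimistic"`,
#'   `"pessimistic"`.
#' @param n_boot,seed bootstrap settings.
#' @return a `bootstrap_summary` with attached `calibration` attribute
#'   (`NULL` when the effect applied directly).
#' @export
bootstrap_run <- function(cohort, spec,
                          scenario = c("published", "realistic",
                                       "optimistic", "pessimistic"),
                          n_boot = 5000L, seed = 1L) {
  stopifnot(inherits(spec, "intervention_spec"))
  scenario <- match.arg(scenario)
  rrs <- scenario_rrs(spec, scenario)
  measure <- spec$published_effect$outcome_measure
  calib <- NULL
  if (measure == "events") {
    rr_s <- rrs$severe; rr_ns <- rrs$total
    calib <- new_calibration_result(
      rrs$total, 0, tibble::tibble(candidate = numeric(0),
                                   modeled = numeric(0)),
      TRUE, measure, "total", "direct application")
  } else if (rrs$severe_given) {
    calib <- calibrate_joint(cohort, published_rr_severe = rrs$severe,
                             published_rr_total = rrs$total,
                             measure = measure)
    if (!calib$converged)
      stop("calibration failed for intervention '", spec$name,
           "', scenario '", scenario, "'")
    rr_s <- calib$rr_common_severe; rr_ns <- calib$rr_common_nonsevere
  } else {
    cp <- calibration_problem(cohort, published_rr = rrs$total,
                              measure = measure, channel = "total")
    calib <- calibrate(cp)
    if (!calib$converged)
      stop("calibration failed for intervention '", spec$name,
           "', scenario '", scenario, "'")
    rr_s <- rr_ns <- calib$rr_common
  }
  res <- bootstrap_prevention(cohort, rr_severe = rr_s,
                              rr_nonsevere = rr_ns,
                              target_filter = spec$target,
                              rule = spec$reporting_criteria,
                              n_boot = n_boot, seed = seed,
                              hac_fraction = spec$hac_fraction)
  attr(res, "calibration") <- calib
  res
}
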