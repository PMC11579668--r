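# per-admission or per-day relevant-event counts for a measure/channel
measure_unit_counts <- function(cohort, measure, channel) {
  ev <- cohort$events
  hypo <- ev[ev$category != "hyper", ]
  if (channel == "severe") hypo <- hypo[hypo$category == "severe_hypo", ]
  if (!nrow(hypo))
    stop("cohort has no relevant events for channel '", channel, "'")
  if (measure == "patients") {
    as.integer(table(hypo$admission_id))
  } else if (measure == "patient_days") {
    as.integer(table(paste(hypo$admission_id, hypo$day)))
  } else stop("unit counts undefined for measure '", measure, "'")
}

# severe/non-severe counts per unit, for the two-channel total measure
measure_unit_counts2 <- function(cohort, measure) {
  ev <- cohort$events
  hypo <- ev[ev$category != "hyper", ]
  if (!nrow(hypo)) stop("cohort has no hypoglycemia events")
  key <- if (measure == "patients") hypo$admission_id
         else paste(hypo$admission_id, hypo$day)
  key <- factor(key)
  s <- tapply(hypo$category == "severe_hypo", key, sum)
  n <- tapply(hypo$category == "nonsevere_hypo", key, sum)
  cbind(severe = as.integer(s), nonsevere = as.integer(n))
}

#' Modeled relative risk on a published outcome measure (closed form)
#'
#' Computes the expected relative risk on a study's reported outcome
#' measure implied by applying an event-level relative risk `rr_common` to
#' every relevant event of the cohort.  With independent event-level
#' prevention, a unit (admission or patient-day) holding `k` relevant
#' events retains at least one with probability `1 - (1 - rr_common)^k`,
#' so the patients / patient-days relative risk is the mean of that
#' quantity over baseline units.  For `measure = "events"` the common
#' measure is returned unchanged.
#'
#' @param cohort an `llee_cohort`.
#' @param rr_common event-level relative risk in `[0, 1]`.
#' @param measure `"events"`, `"patient_days"` or `"patients"`.
#' @param channel `"total"` (all hypoglycemia events) or `"severe"`.
#' @param rr_severe optional: when given together with `channel =
#'   "total"`, severe events use `rr_severe` and non-severe events use
#'   `rr_common` (two-channel form used by [calibrate_joint()]).
#' @return the modeled relative risk (scalar).
#' @examples
#' # every affected admission has exactly 2 events, rr 0.4:
#' adm <- data.frame(admission_id = 1:3, adult = TRUE, obstetric = FALSE,
#'                   surgical = FALSE, icu = FALSE, length_of_stay = 2,
#'                   coded_hac = FALSE)
#' ev <- data.frame(admission_id = rep(1:3, each = 2), day = 0,
#'                  category = "nonsevere_hypo")
#' coh <- cohort(adm, ev)
#' modeled_measure_rr(coh, 0.4, "patients")  # 1 - 0.6^2 = 0.64
#' @export
modeled_measure_rr <- function(cohort, rr_common,
                               measure = c("events", "patient_days",
                                           "patients"),
                               channel = c("total", "severe"),
                               rr_severe = NULL) {
  measure <- match.arg(measure)
  channel <- match.arg(channel)
  check_rr(rr_common, "rr_common")
  if (measure == "events") return(rr_common)
  if (is.null(rr_severe) || channel == "severe") {
    k <- measure_unit_counts(cohort, measure, channel)
    mean(1 - (1 - rr_common)^k)
  } else {
    check_rr(rr_severe, "rr_severe")
    kk <- measure_unit_counts2(cohort, measure)
    mean(1 - (1 - rr_severe)^kk[, "severe"] *
             (1 - rr_common)^kk[, "nonsevere"])
  }
}

# Monte-Carlo counterpart: bootstrap admissions, apply stochastic
# prevention, average the post/pre ratio of units with >= 1 relevant
# remaining event.  A fixed seed per evaluation keeps the objective
# deterministic for the root-finder.
modeled_measure_rr_mc <- function(cohort, rr_common, measure, channel,
                                  rr_severe = NULL, n_boot = 5000L,
                                  seed = 1L) {
  if (measure == "events" && is.null(rr_severe)) return(rr_common)
  p <- prep_prevention(cohort, target_filter = "all")
  rel <- if (channel == "severe") p$severe else rep(TRUE, length(p$severe))
  if (!any(rel))
    stop("cohort has no relevant events for channel '", channel, "'")
  rr_s <- if (is.null(rr_severe)) rr_common else rr_severe
  set.seed(seed)
  ratios <- numeric(n_boot)
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
    rel_e <- rel[ev_idx]
    rr_e <- ifelse(p$severe[ev_idx], rr_s, rr_common)
    remaining <- stats::runif(length(ev_idx)) <= rr_e
    if (measure == "patients") {
      base_units <- tabulate(copy_id[rel_e], nbins = C) > 0L
      rem_units <- tabulate(copy_id[rel_e & remaining], nbins = C) > 0L
      ratios[r] <- sum(rem_units) / sum(base_units)
    } else if (measure == "patient_days") {
      key <- (copy_id - 1) * p$max_day + p$day[ev_idx]
      ratios[r] <- length(unique(key[rel_e & remaining])) /
        length(unique(key[rel_e]))
    } else {  # events measure with two channels
      ratios[r] <- sum(rel_e & remaining) / sum(rel_e)
    }
  }
  mean(ratios)
}

#' Define a calibration problem
#'
#' @param cohort reference `llee_cohort` the modeled measure is computed
#'   on.
#' @param published_rr target relative risk reported by the intervention
#'   study, in `(0, 1]`.
#' @param measure outcome measure the study reported.
#' @param channel `"total"` or `"severe"`.
#' @param tolerance convergence tolerance: absolute difference between
#'   modeled and published relative risk (study default 0.001).
#' @param n_boot bootstrap replicates for Monte-Carlo mode.
#' @param max_iter maximum bisection refinements.
#' @param mc_seed seed fixed per Monte-Carlo objective evaluation.
#' @return a `calibration_problem` object.
#' @export
calibration_problem <- function(cohort, published_rr,
                                measure = c("events", "patient_days",
                                            "patients"),
                                channel = c("total", "severe"),
                                tolerance = 0.001, n_boot = 5000L,
                                max_iter = 60L, mc_seed = 1L) {
  measure <- match.arg(measure)
  channel <- match.arg(channel)
  stopifnot(inherits(cohort, "llee_cohort"))
  if (!is.numeric(published_rr) || published_rr <= 0 || published_rr > 1)
    stop("published_rr must be in (0, 1]")
  if (tolerance <= 0) stop("tolerance must be > 0")
  structure(list(cohort = cohort, published_rr = published_rr,
                 measure = measure, channel = channel,
                 tolerance = tolerance, n_boot = as.integer(n_boot),
                 max_iter = as.integer(max_iter),
                 mc_seed = as.integer(mc_seed)),
            class = "calibration_problem")
}

new_calibration_result <- function(rr_common, achieved_diff, iterations,
                                   converged, measure, channel, mode,
                                   reason = NULL) {
  structure(list(rr_common = rr_common, achieved_diff = achieved_diff,
                 iterations = iterations, converged = converged,
                 measure = measure, channel = channel, mode = mode,
                 reason = reason),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  measure: %s, channel: %s, mode: %s\n",
              x$measure, x$channel, x$mode))
  cat(sprintf("  rr_common = %.6f (achieved diff %.2g, %d refinements)\n",
              x$rr_common, x$achieved_diff, nrow(x$iterations)))
  cat("  converged:", x$converged,
      if (!is.null(x$reason)) paste0(" (", x$reason, ")") else "", "\n")
  invisible(x)
}

#' Calibrate a published relative risk onto the common event-level measure
#'
#' Finds the event-level relative risk whose implied relative risk on the
#' study's reported outcome measure matches the published value within the
#' tolerance.  The modeled measure is strictly increasing in the
#' event-level relative risk, so bisection on `[0, 1]` converges.  For
#' `measure = "events"` the published value is the common measure and is
#' applied directly (zero refinement steps).
#'
#' @param problem a [calibration_problem()].
#' @param mode `"closed_form"` evaluates the expected modeled measure
#'   analytically; `"monte_carlo"` evaluates it by bootstrap simulation
#'   (same scheme as [bootstrap_prevention()]) with a fixed per-evaluation
#'   seed.
#' @return a `calibration_result` with the calibrated `rr_common`, the
#'   achieved absolute difference, the full refinement trace
#'   (`iterations`: candidate vs modeled), and a `converged` flag.  A run
#'   exhausting `max_iter` returns `converged = FALSE`, never a silent
#'   answer.
#' @examples
#' adm <- data.frame(admission_id = 1:4, adult = TRUE, obstetric = FALSE,
#'                   surgical = FALSE, icu = FALSE, length_of_stay = 3,
#'                   coded_hac = FALSE)
#' ev <- data.frame(admission_id = rep(1:4, each = 2), day = 0:1,
#'                  category = "nonsevere_hypo")
#' coh <- cohort(adm, ev)
#' calibrate(calibration_problem(coh, 0.64, measure = "patients"))
#' @export
calibrate <- function(problem, mode = c("closed_form", "monte_carlo")) {
  stopifnot(inherits(problem, "calibration_problem"))
  mode <- match.arg(mode)
  target <- problem$published_rr
  tol <- problem$tolerance
  if (problem$measure == "events")
    return(new_calibration_result(target, 0,
                                  tibble::tibble(candidate = numeric(0),
                                                 modeled = numeric(0)),
                                  TRUE, problem$measure, problem$channel,
                                  "direct application"))
  f <- function(rr) {
    if (mode == "closed_form")
      modeled_measure_rr(problem$cohort, rr, problem$measure,
                         problem$channel)
    else
      modeled_measure_rr_mc(problem$cohort, rr, problem$measure,
                            problem$channel, n_boot = problem$n_boot,
                            seed = problem$mc_seed)
  }
  bisect_rr(f, target, tol, problem$max_iter, problem$measure,
            problem$channel, mode)
}

bisect_rr <- function(f, target, tol, max_iter, measure, channel, mode) {
  lo <- 0; hi <- 1
  trace_cand <- numeric(0); trace_mod <- numeric(0)
  best_rr <- NA_real_; best_diff <- Inf
  converged <- FALSE
  # endpoints first: the inverse map is ill-conditioned near the null
  # effect, so a target attainable at rr = 0 or rr = 1 is answered there
  for (end in c(1, 0)) {
    val <- f(end)
    if (abs(val - target) <= tol) {
      return(new_calibration_result(
        end, abs(val - target),
        tibble::tibble(candidate = end, modeled = val),
        TRUE, measure, channel, mode))
    }
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    trace_cand <- c(trace_cand, mid); trace_mod <- c(trace_mod, val)
    d <- abs(val - target)
    if (d < best_diff) { best_diff <- d; best_rr <- mid }
    if (d <= tol) { converged <- TRUE; break }
    if (val < target) lo <- mid else hi <- mid
  }
  new_calibration_result(
    best_rr, best_diff,
    tibble::tibble(candidate = trace_cand, modeled = trace_mod),
    converged, measure, channel, mode,
    reason = if (!converged) "max_iter exceeded" else NULL)
}

#' Jointly calibrate severe and non-severe channels
#'
#' Calibrates the severe channel against the published severe-event
#' relative risk first, then calibrates the non-severe channel so that the
#' combined all-hypoglycemia measure matches the published total relative
#' risk with the severe channel held fixed.
#'
#' @param cohort an `llee_cohort`.
#' @param published_rr_severe,published_rr_total published relative risks
#'   on `measure` for severe and total hypoglycemia.
#' @param measure `"patient_days"` or `"patients"` (for `"events"` the
#'   published values apply directly).
#' @param tolerance,max_iter as in [calibration_problem()].
#' @return a `joint_calibration` list: `rr_common_severe`,
#'   `rr_common_nonsevere`, `converged`, per-channel `calibration_result`s
#'   (`severe_result`, `total_result`), and `reason` when infeasible.
#' @export
calibrate_joint <- function(cohort, published_rr_severe,
                            published_rr_total,
                            measure = c("patient_days", "patients",
                                        "events"),
                            tolerance = 0.001, max_iter = 60L) {
  measure <- match.arg(measure)
  if (measure == "events") {
    return(structure(list(rr_common_severe = published_rr_severe,
                          rr_common_nonsevere = published_rr_total,
                          converged = TRUE, severe_result = NULL,
                          total_result = NULL, reason = NULL),
                     class = "joint_calibration"))
  }
  ev <- cohort$events
  has_severe <- any(ev$category == "severe_hypo")
  if (!has_severe) {
    # degenerate: no severe events, total channel alone determines the fit
    res <- calibrate(calibration_problem(cohort, published_rr_total,
                                         measure = measure,
                                         channel = "total",
                                         tolerance = tolerance,
                                         max_iter = max_iter))
    return(structure(list(rr_common_severe = published_rr_severe,
                          rr_common_nonsevere = res$rr_common,
                          converged = res$converged, severe_result = NULL,
                          total_result = res, reason = res$reason),
                     class = "joint_calibration"))
  }
  sev <- calibrate(calibration_problem(cohort, published_rr_severe,
                                       measure = measure,
                                       channel = "severe",
                                       tolerance = tolerance,
                                       max_iter = max_iter))
  if (!sev$converged)
    return(structure(list(rr_common_severe = sev$rr_common,
                          rr_common_nonsevere = NA_real_,
                          converged = FALSE, severe_result = sev,
                          total_result = NULL,
                          reason = "severe channel did not converge"),
                     class = "joint_calibration"))
  rr_s <- sev$rr_common
  f <- function(rr_ns)
    modeled_measure_rr(cohort, rr_ns, measure, "total", rr_severe = rr_s)
  f0 <- f(0); f1 <- f(1)
  if (published_rr_total < f0 - tolerance ||
      published_rr_total > f1 + tolerance)
    return(structure(list(rr_common_severe = rr_s,
                          rr_common_nonsevere = NA_real_,
                          converged = FALSE, severe_result = sev,
                          total_result = NULL,
                          reason = sprintf(
                            paste0("infeasible: with severe channel fixed",
                                   " at %.4f the total measure spans ",
                                   "[%.4f, %.4f], target %.4f"),
                            rr_s, f0, f1, published_rr_total)),
                     class = "joint_calibration"))
  tot <- bisect_rr(f, published_rr_total, tolerance, max_iter, measure,
                   "total", "closed_form")
  structure(list(rr_common_severe = rr_s,
                 rr_common_nonsevere = tot$rr_common,
                 converged = tot$converged, severe_result = sev,
                 total_result = tot, reason = tot$reason),
            class = "joint_calibration")
}

#' Serialize a calibration result to JSON
#'
#' Writes the calibrated value, achieved difference, convergence flag and
#' the full refinement trace so calibrations remain auditable.
#'
#' @param x a `calibration_result` or `joint_calibration`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(x, path) {
  ser <- function(r) {
    if (is.null(r)) return(NULL)
    list(rr_common = r$rr_common, achieved_diff = r$achieved_diff,
         converged = r$converged, measure = r$measure,
         channel = r$channel, mode = r$mode, reason = r$reason,
         iterations = as.data.frame(r$iterations))
  }
  obj <- if (inherits(x, "joint_calibration")) {
    list(rr_common_severe = x$rr_common_severe,
         rr_common_nonsevere = x$rr_common_nonsevere,
         converged = x$converged, reason = x$reason,
         severe_result = ser(x$severe_result),
         total_result = ser(x$total_result))
  } else ser(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
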