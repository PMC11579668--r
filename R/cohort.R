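EVENT_CATEGORIES <- c("severe_hypo", "nonsevere_hypo", "hyper")

#' Cohort generator configuration
#'
#' Parameters of the synthetic admission-level cohort generator.  The
#' generator emulates an eligible adult, non-obstetric inpatient population
#' in which a small fraction of admissions experience one or more
#' hypoglycemia events (point-of-care blood glucose < 4.0 mmol/L), with
#' event counts per affected admission drawn from a zero-truncated negative
#' binomial, a severe (< 2.2 mmol/L) / non-severe (2.2 to < 4.0 mmol/L)
#' severity split, background hyperglycemia events (> 15.0 mmol/L), and a
#' coded hospital-acquired-complication (HAC) flag assigned to a fixed
#' fraction of affected admissions.
#'
#' @param n_admissions total admissions generated.
#' @param p_affected probability that an eligible (adult, non-obstetric)
#'   admission has at least one hypoglycemia event.
#' @param event_count_mean mean hypoglycemia events per affected admission
#'   (zero-truncated, so must be >= 1; exactly 1 gives one event each).
#' @param event_count_dispersion negative binomial dispersion (`size`) of
#'   the event-count distribution; ignored when `event_count_mean == 1`.
#' @param severe_share fraction of hypoglycemia events that are severe.
#' @param hyper_rate expected hyperglycemia events per admission-day.
#' @param los_mean mean length of stay in days (stays are `1 + Poisson`).
#' @param surgical_share,icu_share,obstetric_share cohort mix proportions.
#' @param hac_fraction_all,hac_fraction_surgical probability that an
#'   affected admission carries a coded hypoglycemia HAC, for non-surgical
#'   and surgical admissions respectively.
#' @param day_profile `"uniform"` assigns events uniformly over the stay;
#'   `"front_loaded"` weights earlier days (weight `2^(-day/3)`), since
#'   insulin-titration events cluster early in a stay.
#' @param seed integer RNG seed used by [generate_cohort()].
#'
#' @return an object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_admissions = 40000L,
                          p_affected = 0.0169,
                          event_count_mean = 2.702,
                          event_count_dispersion = 1.0,
                          severe_share = 0.10,
                          hyper_rate = 0.04,
                          los_mean = 5,
                          surgical_share = 0.30,
                          icu_share = 0.05,
                          obstetric_share = 0.05,
                          hac_fraction_all = 0.240,
                          hac_fraction_surgical = 0.255,
                          day_profile = c("uniform", "front_loaded"),
                          seed = 1L) {
  day_profile <- match.arg(day_profile)
  cfg <- list(n_admissions = as.integer(n_admissions),
              p_affected = p_affected,
              event_count_mean = event_count_mean,
              event_count_dispersion = event_count_dispersion,
              severe_share = severe_share,
              hyper_rate = hyper_rate,
              los_mean = los_mean,
              surgical_share = surgical_share,
              icu_share = icu_share,
              obstetric_share = obstetric_share,
              hac_fraction_all = hac_fraction_all,
              hac_fraction_surgical = hac_fraction_surgical,
              day_profile = day_profile,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("configuration error: `", name, "` must be a probability in [0, 1]",
           call. = FALSE)
  }
  for (nm in c("p_affected", "severe_share", "surgical_share", "icu_share",
               "obstetric_share", "hac_fraction_all",
               "hac_fraction_surgical"))
    chk_prob(nm)
  if (cfg$n_admissions < 1L)
    stop("configuration error: `n_admissions` must be a positive integer",
         call. = FALSE)
  if (cfg$event_count_mean < 1)
    stop("configuration error: `event_count_mean` must be >= 1 ",
         "(events per affected admission are zero-truncated)", call. = FALSE)
  if (cfg$event_count_mean > 1 &&
      (!is.numeric(cfg$event_count_dispersion) ||
       cfg$event_count_dispersion <= 0))
    stop("configuration error: `event_count_dispersion` must be > 0",
         call. = FALSE)
  if (cfg$hyper_rate < 0)
    stop("configuration error: `hyper_rate` must be >= 0", call. = FALSE)
  if (cfg$los_mean < 1)
    stop("configuration error: `los_mean` must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Construct a cohort from admission and event tables
#'
#' Low-level constructor used by [generate_cohort()], [read_cohort_csv()]
#' and test fixtures.  Validates the invariants the downstream stages rely
#' on: event days fall inside the stay, categories are one of
#' `severe_hypo`, `nonsevere_hypo`, `hyper`, events are sorted by admission
#' and day, and a coded HAC flag is only set on admissions with at least
#' one hypoglycemia event.
#'
#' @param admissions data frame with columns `admission_id`, `adult`,
#'   `obstetric`, `surgical`, `icu`, `length_of_stay`, `coded_hac`.
#' @param events data frame with columns `admission_id`, `day` (0-based,
#'   0 = admission day), `category`, and optionally `prevented` (defaults
#'   to `FALSE`).
#' @param config optional `cohort_config` recorded as an attribute.
#'
#' @return an object of class `llee_cohort`: a list with tibble elements
#'   `admissions` and `events`.
#' @export
cohort <- function(admissions, events, config = NULL) {
  adm_cols <- c("admission_id", "adult", "obstetric", "surgical", "icu",
                "length_of_stay", "coded_hac")
  missing_cols <- setdiff(adm_cols, names(admissions))
  if (length(missing_cols))
    stop("admissions table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  ev_cols <- c("admission_id", "day", "category")
  missing_cols <- setdiff(ev_cols, names(events))
  if (length(missing_cols))
    stop("events table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"prevented" %in% names(events))
    events$prevented <- logical(nrow(events))

  admissions <- tibble::as_tibble(admissions)[, adm_cols]
  events <- tibble::as_tibble(events)[, c(ev_cols, "prevented")]
  if (anyDuplicated(admissions$admission_id))
    stop("duplicate admission_id in admissions table")
  if (!all(events$category %in% EVENT_CATEGORIES))
    stop("event category must be one of: ",
         paste(EVENT_CATEGORIES, collapse = ", "))
  if (nrow(events)) {
    if (!all(events$admission_id %in% admissions$admission_id))
      stop("events reference unknown admission_id")
    los <- admissions$length_of_stay[match(events$admission_id,
                                           admissions$admission_id)]
    if (any(events$day < 0) || any(events$day >= los))
      stop("event day must satisfy 0 <= day < length_of_stay")
    ord <- order(match(events$admission_id, admissions$admission_id),
                 events$day)
    events <- events[ord, ]
  }
  hypo_ids <- unique(events$admission_id[events$category != "hyper"])
  bad_hac <- admissions$coded_hac & !(admissions$admission_id %in% hypo_ids)
  if (any(bad_hac))
    stop("coded_hac set on admissions without any hypoglycemia event: ",
         paste(utils::head(admissions$admission_id[bad_hac], 5),
               collapse = ", "))
  structure(list(admissions = admissions, events = events),
            class = "llee_cohort", config = config)
}

#' @export
print.llee_cohort <- function(x, ...) {
  s <- summarize_baseline(x)
  cat("<llee_cohort>\n")
  cat(sprintf("  admissions: %d (affected: %d)\n",
              s$n_admissions, s$n_affected))
  cat(sprintf("  hypoglycemia events: %d (severe: %d, non-severe: %d)\n",
              s$n_hypo_events, s$n_severe_events, s$n_nonsevere_events))
  cat(sprintf("  hyperglycemia events: %d\n", s$n_hyper_events))
  cat(sprintf("  coded HACs: %d (fraction of affected: %s)\n",
              s$n_coded_hac,
              if (is.na(s$hac_fraction)) "undefined"
              else sprintf("%.1f%%", 100 * s$hac_fraction)))
  invisible(x)
}

#' Generate a synthetic admission-level cohort
#'
#' Draws a cohort of admissions with categorized blood-glucose events
#' according to a [cohort_config()].  Generation is deterministic given the
#' config (including its seed).
#'
#' @param config a `cohort_config`.
#' @return an `llee_cohort`.
#' @examples
#' cfg <- cohort_config(n_admissions = 2000, seed = 7)
#' coh <- generate_cohort(cfg)
#' summarize_baseline(coh)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_admissions

  obstetric <- stats::runif(n) < config$obstetric_share
  surgical <- stats::runif(n) < config$surgical_share
  icu <- stats::runif(n) < config$icu_share
  los <- 1L + stats::rpois(n, max(config$los_mean - 1, 0))
  eligible <- !obstetric                      # all generated patients adult
  affected <- eligible & stats::runif(n) < config$p_affected

  n_aff <- sum(affected)
  if (n_aff > 0) {
    if (config$event_count_mean == 1) {
      k <- rep(1L, n_aff)
    } else {
      mu <- ztnb_mu_for_mean(config$event_count_mean,
                             config$event_count_dispersion)
      k <- rztnb(n_aff, mu = mu, size = config$event_count_dispersion)
    }
  } else k <- integer(0)

  hypo_adm <- rep(which(affected), k)
  n_hypo <- length(hypo_adm)
  severe <- stats::runif(n_hypo) < config$severe_share
  hypo_day <- draw_event_days(los[hypo_adm], config$day_profile)

  n_hyper_per_adm <- stats::rpois(n, config$hyper_rate * los)
  hyper_adm <- rep(seq_len(n), n_hyper_per_adm)
  hyper_day <- draw_event_days(los[hyper_adm], config$day_profile)

  hac_p <- ifelse(surgical, config$hac_fraction_surgical,
                  config$hac_fraction_all)
  coded_hac <- affected & stats::runif(n) < hac_p

  admissions <- tibble::tibble(
    admission_id = seq_len(n),
    adult = TRUE,
    obstetric = obstetric,
    surgical = surgical,
    icu = icu,
    length_of_stay = los,
    coded_hac = coded_hac)
  events <- tibble::tibble(
    admission_id = c(hypo_adm, hyper_adm),
    day = c(hypo_day, hyper_day),
    category = c(ifelse(severe, "severe_hypo", "nonsevere_hypo"),
                 rep("hyper", length(hyper_adm))),
    prevented = FALSE)
  cohort(admissions, events, config = config)
}

draw_event_days <- function(los, profile) {
  if (!length(los)) return(integer(0))
  if (profile == "uniform") {
    as.integer(floor(stats::runif(length(los)) * los))
  } else {
    # front-loaded: geometric-style decay, weight 2^(-day/3)
    vapply(los, function(l) {
      w <- 2^(-(0:(l - 1)) / 3)
      sample.int(l, 1L, prob = w) - 1L
    }, integer(1))
  }
}

#' Baseline targets for the generator fit
#'
#' @param n_affected admissions with at least one hypoglycemia event.
#' @param n_events total hypoglycemia events across those admissions.
#' @param p_multi share of affected admissions with two or more events.
#' @param n_admissions eligible-population size the generator should use.
#' @return a `baseline_targets` list.
#' @export
baseline_targets <- function(n_affected = 641, n_events = 1732,
                             p_multi = 0.63, n_admissions = 40000L) {
  stopifnot(n_affected > 0, n_events >= n_affected, n_admissions > 0)
  structure(list(n_affected = n_affected, n_events = n_events,
                 p_multi = p_multi, n_admissions = as.integer(n_admissions)),
            class = "baseline_targets")
}

#' Fit the cohort generator to baseline targets
#'
#' Moment-matches the zero-truncated event-count distribution so that its
#' implied mean events per affected admission equals
#' `n_events / n_affected` and its probability of two or more events equals
#' `p_multi`, and sets `p_affected` so the expected number of affected
#' admissions equals `n_affected` among eligible (non-obstetric)
#' admissions.
#'
#' @param targets a [baseline_targets()] object.
#' @param ... further arguments passed to [cohort_config()] (e.g. `seed`,
#'   `severe_share`, `obstetric_share`).
#' @return a complete `cohort_config`.
#' @examples
#' cfg <- fit_generator(baseline_targets(), seed = 42)
#' cfg$event_count_mean  # 1732 / 641
#' @export
fit_generator <- function(targets, ...) {
  stopifnot(inherits(targets, "baseline_targets"))
  mean_target <- targets$n_events / targets$n_affected
  if (mean_target < 1)
    stop("infeasible targets: mean events per affected admission < 1")
  fit <- ztnb_fit(mean_target,
                  if (mean_target == 1) 0 else targets$p_multi)
  extra <- list(...)
  obstetric_share <- if (!is.null(extra$obstetric_share))
    extra$obstetric_share else formals(cohort_config)$obstetric_share
  p_aff <- targets$n_affected /
    (targets$n_admissions * (1 - obstetric_share))
  if (p_aff > 1)
    stop("infeasible targets: implied p_affected > 1; increase n_admissions")
  args <- c(list(n_admissions = targets$n_admissions, p_affected = p_aff,
                 event_count_mean = mean_target,
                 event_count_dispersion = if (fit$degenerate) 1 else fit$size),
            extra)
  do.call(cohort_config, args)
}

#' Summarize a cohort
#'
#' Counts admissions, events (by category), patient-days with at least one
#' hypoglycemia event, coded HACs and the HAC fraction.  Only events not
#' flagged `prevented` are counted, so on a freshly generated cohort this
#' is the baseline summary, and after [apply_intervention()] it summarizes
#' the residual cohort.
#'
#' @param x an `llee_cohort`.
#' @return a one-row tibble with columns `n_admissions`, `n_affected`,
#'   `n_hypo_events`, `n_severe_events`, `n_nonsevere_events`,
#'   `n_hyper_events`, `n_hypo_patient_days`, `p_multi` (share of affected
#'   admissions with >= 2 hypoglycemia events), `n_coded_hac` and
#'   `hac_fraction` (`NA` when no admission is affected).
#' @export
summarize_baseline <- function(x) {
  stopifnot(inherits(x, "llee_cohort"))
  ev <- x$events[!x$events$prevented, ]
  hypo <- ev[ev$category != "hyper", ]
  per_adm <- table(hypo$admission_id)
  n_aff <- length(per_adm)
  tibble::tibble(
    n_admissions = nrow(x$admissions),
    n_affected = n_aff,
    n_hypo_events = nrow(hypo),
    n_severe_events = sum(hypo$category == "severe_hypo"),
    n_nonsevere_events = sum(hypo$category == "nonsevere_hypo"),
    n_hyper_events = sum(ev$category == "hyper"),
    n_hypo_patient_days = nrow(unique(hypo[, c("admission_id", "day")])),
    p_multi = if (n_aff) mean(per_adm >= 2) else NA_real_,
    n_coded_hac = sum(x$admissions$coded_hac),
    hac_fraction = if (n_aff) sum(x$admissions$coded_hac) / n_aff
                   else NA_real_)
}

#' Read and write a cohort as CSV
#'
#' The on-disk schema is two CSV files: an admissions table
#' (`admission_id, adult, obstetric, surgical, icu, length_of_stay,
#' coded_hac`) and an events table (`admission_id, day, category,
#' prevented`).  Round-trips exactly through [cohort()] validation.
#'
#' @param x an `llee_cohort`.
#' @param admissions_file,events_file CSV paths.
#' @return `write_cohort_csv` returns the paths invisibly;
#'   `read_cohort_csv` returns an `llee_cohort`.
#' @export
write_cohort_csv <- function(x, admissions_file, events_file) {
  stopifnot(inherits(x, "llee_cohort"))
  utils::write.csv(x$admissions, admissions_file, row.names = FALSE)
  utils::write.csv(x$events, events_file, row.names = FALSE)
  invisible(c(admissions = admissions_file, events = events_file))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(admissions_file, events_file) {
  adm <- utils::read.csv(admissions_file, stringsAsFactors = FALSE)
  ev <- utils::read.csv(events_file, stringsAsFactors = FALSE)
  for (col in c("adult", "obstetric", "surgical", "icu", "coded_hac"))
    adm[[col]] <- as.logical(adm[[col]])
  if (!is.null(ev$prevented)) ev$prevented <- as.logical(ev$prevented)
  cohort(adm, ev)
}
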