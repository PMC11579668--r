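#' Pipeline run configuration
#'
#' @param cohort_config a [cohort_config()]; ignored when cohort CSV paths
#'   are supplied.
#' @param cohort_files optional named character vector
#'   `c(admissions = ..., events = ...)` pointing at a cohort in the
#'   documented CSV schema.
#' @param interventions list of [intervention_spec()] objects or YAML
#'   paths.
#' @param scenarios subset of `published`, `realistic`, `optimistic`,
#'   `pessimistic` to run per intervention (scenarios an intervention
#'   lacks elicited values for are skipped with a log line).
#' @param n_boot bootstrap replicates per scenario (study default 5,000).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param cost a [cost_params()].
#' @param surveys_completed completed surveys per year for interventions
#'   whose resource profile includes a per-cycle nursing component.
#' @param output_dir directory artifacts are written to.
#' @param log_level `"quiet"`, `"info"` or `"verbose"`.
#' @return a `run_config` object.
#' @export
run_config <- function(cohort_config = NULL, cohort_files = NULL,
                       interventions, scenarios = c("published",
                                                    "realistic",
                                                    "optimistic",
                                                    "pessimistic"),
                       n_boot = 5000L, seed = 1L,
                       cost = cost_params(), surveys_completed = 0,
                       output_dir = tempfile("llee_run_"),
                       log_level = c("info", "quiet", "verbose")) {
  log_level <- match.arg(log_level)
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if (is.null(cohort_config) && is.null(cohort_files))
    stop("either cohort_config or cohort_files must be supplied")
  if (!is.null(cohort_files)) {
    if (!all(c("admissions", "events") %in% names(cohort_files)))
      stop("cohort_files must name 'admissions' and 'events' paths")
    missing <- cohort_files[!file.exists(cohort_files)]
    if (length(missing))
      stop("cohort file does not exist: ", paste(missing, collapse = ", "))
  }
  interventions <- lapply(interventions, function(x) {
    if (inherits(x, "intervention_spec")) return(x)
    if (is.character(x)) {
      if (!file.exists(x)) stop("intervention spec file not found: ", x)
      return(read_intervention_spec(x))
    }
    stop("interventions must be intervention_spec objects or YAML paths")
  })
  structure(list(cohort_config = cohort_config,
                 cohort_files = cohort_files,
                 interventions = interventions, scenarios = scenarios,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 cost = cost, surveys_completed = surveys_completed,
                 output_dir = output_dir, log_level = log_level),
            class = "run_config")
}

pipeline_log <- function(level, config, ..., t0 = NULL) {
  ranks <- c(quiet = 0, info = 1, verbose = 2)
  if (ranks[[config$log_level]] < ranks[[level]]) return(invisible())
  elapsed <- if (!is.null(t0))
    sprintf(" [%.2fs]", as.numeric(Sys.time()) - t0) else ""
  message(format(Sys.time(), "%H:%M:%S "), ..., elapsed)
}

# derived per-stage seeds, kept well below 2^31
stage_seed <- function(master, offset) (master * 97L + offset) %% 2147483L

#' Run the evaluation pipeline end-to-end
#'
#' Generates (or loads) the cohort, summarizes the baseline, calibrates
#' each intervention's relative risks for every requested scenario, runs
#' the bootstrap prevention engine, assembles cost-consequence tables and
#' joint severe/non-severe event distributions, and writes all artifacts
#' plus a machine-readable run manifest to the output directory.  The
#' `published` scenario corresponds to a preliminary evaluation (published
#' effects); the elicited scenarios form the final evaluation.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with `baseline`, per-intervention results
#'   (`calibrations`, `bootstraps`, `cost_table`, `joint_distribution`),
#'   and `manifest`.  Identical configs yield byte-identical artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  coh <- stage("cohort", {
    if (!is.null(config$cohort_files))
      read_cohort_csv(config$cohort_files[["admissions"]],
                      config$cohort_files[["events"]])
    else generate_cohort(config$cohort_config)
  })
  pipeline_log("info", config, "cohort ready: ",
               nrow(coh$admissions), " admissions", t0 = t0)

  baseline <- stage("baseline_summary", summarize_baseline(coh))
  utils::write.csv(baseline,
                   file.path(config$output_dir, "baseline_summary.csv"),
                   row.names = FALSE)

  results <- list()
  for (spec in config$interventions) {
    iv <- list(spec = spec, calibrations = list(), bootstraps = list())
    slug <- gsub("[^a-z0-9]+", "_", tolower(spec$name))
    for (sc in config$scenarios) {
      if (sc != "published" && (is.null(spec$elicited_rrs) ||
                                is.null(spec$elicited_rrs[[sc]]))) {
        pipeline_log("verbose", config, spec$name, ": no elicited values ",
                     "for scenario '", sc, "', skipped")
        next
      }
      bs <- stage(paste0("bootstrap:", spec$name, ":", sc),
                  bootstrap_run(coh, spec, scenario = sc,
                                n_boot = config$n_boot,
                                seed = stage_seed(config$seed,
                                                  match(sc, c("published",
                                                              "realistic",
                                                              "optimistic",
                                                              "pessimistic")))))
      iv$bootstraps[[sc]] <- bs
      calib <- attr(bs, "calibration")
      iv$calibrations[[sc]] <- calib
      if (!is.null(calib))
        write_calibration_json(calib,
                               file.path(config$output_dir,
                                         sprintf("calibration_%s_%s.json",
                                                 slug, sc)))
      pipeline_log("info", config, spec$name, " / ", sc, ": ",
                   sprintf("%.1f patients fully prevented",
                           bs$means[["patients_fully_prevented"]]),
                   t0 = t0)
    }
    if (length(iv$bootstraps)) {
      surveys <- if (!is.null(spec$resources) &&
                     "nursing" %in% names(spec$resources$per_cycle_components))
        config$surveys_completed else 0
      iv$cost_table <- stage(paste0("cost_table:", spec$name),
                             assemble_cost_table(iv$bootstraps,
                                                 params = config$cost,
                                                 profile = spec$resources,
                                                 surveys_completed = surveys))
      write_cost_table_csv(iv$cost_table,
                           file.path(config$output_dir,
                                     sprintf("cost_consequence_%s.csv",
                                             slug)))
      ref <- iv$bootstraps[[if ("realistic" %in% names(iv$bootstraps))
        "realistic" else names(iv$bootstraps)[1]]]
      iv$joint_distribution <- histogram_to_table(ref)
      utils::write.csv(iv$joint_distribution,
                       file.path(config$output_dir,
                                 sprintf("joint_distribution_%s.csv",
                                         slug)),
                       row.names = FALSE)
    }
    results[[spec$name]] <- iv
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lleesim")),
    seed = config$seed, n_boot = config$n_boot,
    scenarios = config$scenarios,
    surveys_completed = config$surveys_completed,
    cohort_config = if (!is.null(config$cohort_config))
      unclass(config$cohort_config) else NULL,
    cohort_files = config$cohort_files,
    cost_params = unclass(config$cost),
    interventions = lapply(config$interventions, function(s)
      list(name = s$name, target = s$target,
           published_effect = s$published_effect,
           elicited_rrs = s$elicited_rrs,
           reporting_criteria = if (!is.null(s$reporting_criteria))
             unclass(s$reporting_criteria) else NULL,
           hac_fraction = s$hac_fraction)))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  pipeline_log("info", config, "pipeline complete", t0 = t0)
  invisible(list(baseline = baseline, results = results,
                 manifest = manifest, output_dir = config$output_dir))
}

# long-format average joint histogram from a bootstrap summary
histogram_to_table <- function(bs) {
  hb <- bs$hist_baseline; hr <- bs$hist_remaining
  grid <- expand.grid(n_severe = as.integer(rownames(hb)),
                      n_nonsevere = as.integer(colnames(hb)))
  tibble::tibble(n_severe = grid$n_severe,
                 n_nonsevere = grid$n_nonsevere,
                 admissions_baseline = as.vector(hb),
                 admissions_after = as.vector(hr),
                 delta = as.vector(hr) - as.vector(hb))
}

#' Joint severe/non-severe event distribution before and after an
#' intervention
#'
#' Counts admissions per (severe-event count, non-severe-event count)
#' cell among admissions affected at baseline, before and after
#' prevention, including the `(0, 0)` cell for admissions whose events
#' were all prevented.
#'
#' @param cohort_before,cohort_after aligned `llee_cohort`s: the same
#'   admissions, with `prevented` flags set on the "after" cohort (e.g.
#'   from [apply_intervention()]).
#' @return a tibble with columns `n_severe`, `n_nonsevere`,
#'   `admissions_baseline`, `admissions_after`, `delta`.
#' @export
joint_event_distribution <- function(cohort_before, cohort_after) {
  stopifnot(inherits(cohort_before, "llee_cohort"),
            inherits(cohort_after, "llee_cohort"))
  if (!identical(cohort_before$admissions$admission_id,
                 cohort_after$admissions$admission_id))
    stop("cohorts are not aligned: admission ids differ")
  count_cells <- function(coh, only_remaining) {
    ev <- coh$events
    hypo <- ev[ev$category != "hyper", ]
    if (only_remaining) keep <- !hypo$prevented else keep <- TRUE
    ids <- factor(hypo$admission_id,
                  levels = unique(hypo$admission_id))
    s <- tapply(hypo$category == "severe_hypo" & keep, ids, sum)
    n <- tapply(hypo$category == "nonsevere_hypo" & keep, ids, sum)
    data.frame(id = names(s), s = as.integer(s), n = as.integer(n))
  }
  before <- count_cells(cohort_before, only_remaining = FALSE)
  after <- count_cells(cohort_after, only_remaining = TRUE)
  if (!setequal(before$id, after$id))
    stop("cohorts are not aligned: affected admissions differ")
  after <- after[match(before$id, after$id), ]
  smax <- max(before$s); nmax <- max(before$n)
  tab <- function(s, n) as.vector(table(factor(s, levels = 0:smax),
                                        factor(n, levels = 0:nmax)))
  grid <- expand.grid(n_severe = 0:smax, n_nonsevere = 0:nmax)
  tibble::tibble(n_severe = grid$n_severe,
                 n_nonsevere = grid$n_nonsevere,
                 admissions_baseline = tab(before$s, before$n),
                 admissions_after = tab(after$s, after$n),
                 delta = tab(after$s, after$n) - tab(before$s, before$n))
}
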