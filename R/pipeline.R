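#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults matching
#' the reference paradigm: moderate-difficulty variant, adjusted p < 0.01
#' with Bonferroni m = 5, at-least-4-of-5 decision rule, rank-sum test on
#' task vs pooled rests, two-sided with an explicit median-direction
#' requirement, artifact flagging off.
#'
#' @param variant Paradigm variant.
#' @param task_duration_s,rest_duration_s Epoch durations; `NULL` uses the
#'   variant defaults (30/30 s moderate, 15/15 s simple).
#' @param method,alternative,rest_pooling Test configuration.
#' @param alpha,m,k Decision-rule parameters.
#' @param artifact_flagging,min_diameter_mm,max_step_mm Artifact options.
#' @param seed Seed for any simulation step.
#' @return A `pupil_config` list.
#' @export
pupil_config <- function(variant = "moderate", task_duration_s = NULL,
                         rest_duration_s = NULL, method = "rank_sum",
                         alternative = "two_sided", rest_pooling = "pooled",
                         alpha = 0.01, m = 5, k = 4,
                         artifact_flagging = FALSE, min_diameter_mm = 1,
                         max_step_mm = 1, seed = 1L) {
  cfg <- list(variant = variant, task_duration_s = task_duration_s,
              rest_duration_s = rest_duration_s, method = method,
              alternative = alternative, rest_pooling = rest_pooling,
              alpha = alpha, m = m, k = k,
              artifact_flagging = artifact_flagging,
              min_diameter_mm = min_diameter_mm, max_step_mm = max_step_mm,
              seed = as.integer(seed))
  structure(cfg, class = "pupil_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pupil_config` returns a `pupil_config`;
#'   `write_pupil_config` returns `path` invisibly.
#' @export
read_pupil_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pupil_config, raw[names(raw) %in% names(formals(pupil_config))])
}

#' @param config A `pupil_config`.
#' @rdname read_pupil_config
#' @export
write_pupil_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_schedule <- function(config) {
  build_schedule(config$variant, config$task_duration_s,
                 config$rest_duration_s)
}

#' Analyze a cohort of recordings end to end
#'
#' Runs QC screening (when screening data are supplied), fits [pupilcf()] to
#' every included recording, and aggregates the group summary. When
#' `output_dir` is given, writes deterministic report files: per-subject task
#' comparison tables, a subject summary, the group summary table, and a run
#' manifest echoing the resolved configuration. QC-excluded subjects are
#' reported in the subject summary with their failure reasons, never silently
#' dropped.
#'
#' @param recordings Either a directory of recording CSVs (in the
#'   [write_pupil_csv()] dialect) or a list of `pupil_recording` objects.
#' @param config A `pupil_config`.
#' @param screens Optional screening table for [screen_cohort()]; subjects
#'   failing QC are excluded from analysis and listed in the outputs.
#' @param group_label Group label for the summary.
#' @param output_dir Optional directory for report CSVs.
#' @return List with `fits` (named list of `pupilcf`), `group` (a
#'   `group_summary`), `excluded` (data frame of QC-excluded subjects) and
#'   `config`.
#' @export
analyze_cohort <- function(recordings, config = pupil_config(),
                           screens = NULL, group_label = "group",
                           output_dir = NULL) {
  if (is.character(recordings)) {
    if (!dir.exists(recordings))
      stop("input directory not found: ", recordings, call. = FALSE)
    files <- sort(list.files(recordings, pattern = "\\.csv$",
                             full.names = TRUE))
    files <- files[!basename(files) %in% c("truth.csv", "qc.csv")]
    if (length(files) == 0L)
      stop("no recording CSVs in ", recordings, call. = FALSE)
    recordings <- lapply(files, read_pupil_csv)
  }
  stopifnot(is.list(recordings),
            all(vapply(recordings, inherits, logical(1), "pupil_recording")))
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  names(recordings) <- ids

  excluded <- data.frame(subject_id = character(0), reasons = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(screens)) {
    qc <- screen_cohort(screens)
    excluded <- qc[!qc$include, c("subject_id", "reasons")]
    keep <- ids %in% qc$subject_id[qc$include] | !ids %in% qc$subject_id
    recordings <- recordings[keep]
  }
  if (length(recordings) == 0L)
    stop("no recordings left to analyze after QC", call. = FALSE)

  schedule <- config_schedule(config)
  fits <- lapply(recordings, function(rec)
    pupilcf(rec, schedule, alpha = config$alpha, m = config$m, k = config$k,
            method = config$method, alternative = config$alternative,
            rest_pooling = config$rest_pooling,
            artifact_flagging = config$artifact_flagging,
            min_diameter_mm = config$min_diameter_mm,
            max_step_mm = config$max_step_mm))
  group <- summarize_group(fits, group_label, k = config$k)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (fit in fits) {
      tab <- fit$comparisons
      utils::write.csv(tab, file.path(output_dir,
                                      paste0(fit$subject_id, "_tasks.csv")),
                       row.names = FALSE)
    }
    subj <- data.frame(
      subject_id = c(vapply(fits, function(f) f$subject_id, character(1)),
                     excluded$subject_id),
      included = c(rep(TRUE, length(fits)), rep(FALSE, nrow(excluded))),
      n_significant = c(vapply(fits, function(f) f$n_significant,
                               numeric(1)), rep(NA, nrow(excluded))),
      command_following = c(vapply(fits, function(f) f$command_following,
                                   logical(1)), rep(NA, nrow(excluded))),
      qc_reasons = c(rep("", length(fits)), excluded$reasons),
      stringsAsFactors = FALSE
    )
    utils::write.csv(subj, file.path(output_dir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(group),
                     file.path(output_dir, "group_summary.csv"),
                     row.names = FALSE)
    write_pupil_config(config, file.path(output_dir, "run_manifest.yaml"))
  }

  list(fits = fits, group = group, excluded = excluded, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits one recording CSV per subject in the standard dialect, a
#' `truth.csv` ground-truth table (`subject_id`, `responder`, `amplitude_mm`,
#' `seed`), and the resolved generator parameters as
#' `cohort_provenance.yaml`.
#'
#' @param spec A `cohort_spec`.
#' @param dir Output directory (created if needed).
#' @return The cohort list from [simulate_cohort()], invisibly.
#' @export
write_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- build_schedule(spec$variant)
  cohort <- simulate_cohort(spec, schedule)
  for (subj in cohort)
    write_pupil_csv(subj$recording,
                    file.path(dir, paste0(subj$subject_id, ".csv")))
  truth <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    responder = vapply(cohort, `[[`, logical(1), "responder"),
    amplitude_mm = ifelse(vapply(cohort, `[[`, logical(1), "responder"),
                          spec$amplitude_mm, 0),
    seed = vapply(cohort, `[[`, integer(1), "seed"))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  prov <- c(unclass(spec$params),
            list(n_subjects = spec$n_subjects,
                 responder_fraction = spec$responder_fraction,
                 amplitude_mm = spec$amplitude_mm, variant = spec$variant))
  yaml::write_yaml(prov, file.path(dir, "cohort_provenance.yaml"))
  invisible(cohort)
}
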