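# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# fixed, documented splitting rule: derive per-unit seeds from a master seed
# so cohorts are extensible without reshuffling earlier subjects
derive_seed <- function(master, i) {
  as.integer((as.double(master %% 100003L) * 20011 + as.double(i) * 7919) %%
               2147483647) + 1L
}

#' Simulation parameters for synthetic pupil recordings
#'
#' The generative model is the minimal structure reproducing the morphology
#' of real task recordings: diameter(t) = baseline + drift(t) + a * r(t) +
#' noise(t), where r(t) relaxes first-order (time constant `tau_s`) toward 1
#' inside task epochs and toward 0 inside rest epochs, drift is a slow
#' sinusoid, noise is i.i.d. Gaussian, and blinks are contiguous runs of
#' invalid samples placed by a seeded Poisson process.
#'
#' @param baseline_mm Resting pupil diameter (mm), in (1, 9).
#' @param dilation_amplitude_mm Asymptotic task-evoked increase (mm); 0 gives
#'   a non-responder.
#' @param tau_s First-order rise/decay time constant (s), > 0.
#' @param drift_amplitude_mm,drift_period_s Sinusoidal baseline wander.
#' @param noise_sd_mm Additive Gaussian noise SD (mm).
#' @param blink_rate_per_min Expected dropout events per minute.
#' @param blink_duration_s Dropout length (s).
#' @param sampling_rate_hz Sampling rate (default 30 Hz).
#' @param seed Integer seed; a fixed seed makes the recording bit-identical.
#' @return A `sim_params` list.
#' @export
sim_params <- function(baseline_mm = 4.5, dilation_amplitude_mm = 0.5,
                       tau_s = 2, drift_amplitude_mm = 0.1,
                       drift_period_s = 90, noise_sd_mm = 0.05,
                       blink_rate_per_min = 4, blink_duration_s = 0.3,
                       sampling_rate_hz = 30, seed = 1L) {
  if (baseline_mm <= 1 || baseline_mm >= 9)
    stop("`baseline_mm` must lie in (1, 9)", call. = FALSE)
  if (tau_s <= 0) stop("`tau_s` must be positive", call. = FALSE)
  for (v in list(dilation_amplitude_mm, drift_amplitude_mm, noise_sd_mm,
                 blink_rate_per_min, blink_duration_s))
    if (v < 0) stop("scales must be non-negative", call. = FALSE)
  if (drift_period_s <= 0 || sampling_rate_hz <= 0)
    stop("periods and rates must be positive", call. = FALSE)
  structure(list(baseline_mm = baseline_mm,
                 dilation_amplitude_mm = dilation_amplitude_mm,
                 tau_s = tau_s, drift_amplitude_mm = drift_amplitude_mm,
                 drift_period_s = drift_period_s, noise_sd_mm = noise_sd_mm,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_duration_s = blink_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate one pupil recording over a paradigm schedule
#'
#' See [sim_params()] for the generative model. The task-response kernel is
#' integrated in closed form per epoch, so no numerical ODE stepping is
#' involved. Diameters are clamped to (0.1, 10\] mm so extreme noise draws
#' cannot produce physically impossible values. The output is a pure
#' function of `(schedule, params)`: the same seed gives a bit-identical
#' recording, and the caller's RNG state is left untouched.
#'
#' @param schedule A `paradigm_schedule`.
#' @param params A `sim_params`.
#' @param subject_id,eye Metadata for the recording.
#' @return List with `recording` (a `pupil_recording`) and `responder`
#'   (logical ground truth: `dilation_amplitude_mm > 0`).
#' @export
simulate_recording <- function(schedule, params = sim_params(),
                               subject_id = "sim", eye = "right") {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(schedule) || nrow(schedule) == 0L)
    stop("empty schedule", call. = FALSE)
  fs <- params$sampling_rate_hz
  span <- max(schedule$end_s)
  n <- floor(span * fs)
  t <- (seq_len(n) - 1L) / fs

  # first-order task-response kernel, closed form within each epoch
  r <- numeric(n)
  r0 <- 0
  for (i in seq_len(nrow(schedule))) {
    target <- if (schedule$kind[i] == "task") 1 else 0
    in_ep <- t >= schedule$start_s[i] & t < schedule$end_s[i]
    te <- t[in_ep] - schedule$start_s[i]
    r[in_ep] <- target + (r0 - target) * exp(-te / params$tau_s)
    dur <- schedule$end_s[i] - schedule$start_s[i]
    r0 <- target + (r0 - target) * exp(-dur / params$tau_s)
  }

  drift <- params$drift_amplitude_mm *
    sin(2 * pi * t / params$drift_period_s)

  with_seed(params$seed, {
    noise <- stats::rnorm(n, 0, params$noise_sd_mm)
    d <- params$baseline_mm + drift + params$dilation_amplitude_mm * r + noise
    d <- pmin(pmax(d, 0.1), 10)

    valid <- rep(TRUE, n)
    n_blinks <- stats::rpois(1, params$blink_rate_per_min * span / 60)
    if (n_blinks > 0) {
      starts <- stats::runif(n_blinks, 0, span)
      for (b in starts)
        valid[t >= b & t < b + params$blink_duration_s] <- FALSE
    }
    d[!valid] <- NA_real_
    rec <- pupil_recording(t, d, valid, subject_id, eye, fs)
    list(recording = rec, responder = params$dilation_amplitude_mm > 0)
  })
}

#' Cohort specification for simulation
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param responder_fraction Probability that a subject carries a non-zero
#'   dilation amplitude (ground-truth command following).
#' @param amplitude_mm Dilation amplitude given to responders (mm).
#' @param params Shared `sim_params` template; its `seed` is the cohort
#'   master seed from which per-subject seeds are derived.
#' @param variant Paradigm variant for the schedule.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 20, responder_fraction = 0.7,
                        amplitude_mm = 0.5, params = sim_params(),
                        variant = c("moderate", "simple")) {
  variant <- match.arg(variant)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("`responder_fraction` must lie in [0, 1]", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 responder_fraction = responder_fraction,
                 amplitude_mm = amplitude_mm, params = params,
                 variant = variant),
            class = "cohort_spec")
}

#' Simulate a cohort of pupil recordings with known ground truth
#'
#' Responder labels are drawn once from the master seed; each subject's
#' recording then uses a seed derived deterministically from the master seed
#' and the subject index, so extending `n_subjects` never reshuffles earlier
#' subjects.
#'
#' @param spec A `cohort_spec`.
#' @param schedule Optional pre-built schedule (defaults to the spec variant).
#' @return List of per-subject lists: `subject_id`, `recording`, `responder`,
#'   `seed`.
#' @export
simulate_cohort <- function(spec, schedule = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(schedule)) schedule <- build_schedule(spec$variant)
  master <- spec$params$seed
  responder <- with_seed(master,
                         stats::runif(spec$n_subjects) < spec$responder_fraction)
  lapply(seq_len(spec$n_subjects), function(i) {
    p <- spec$params
    p$dilation_amplitude_mm <- if (responder[i]) spec$amplitude_mm else 0
    p$seed <- derive_seed(master, i)
    id <- sprintf("sim%03d", i)
    sim <- simulate_recording(schedule, p, subject_id = id)
    list(subject_id = id, recording = sim$recording,
         responder = responder[i], seed = p$seed)
  })
}

#' Operating characteristics of the detection paradigm by simulation
#'
#' Runs the full detection pipeline over simulated cohorts and estimates the
#' per-task significant-dilation rate and the subject-level decision rate,
#' split by ground truth (false-positive rates among non-responders, power
#' among responders), with binomial Monte-Carlo standard errors.
#'
#' @param spec A `cohort_spec`; its `responder_fraction` and `amplitude_mm`
#'   set the truth mixture.
#' @param n_reps Number of cohort replicates (default 1).
#' @param alpha,m,k,method,alternative,rest_pooling Detection configuration;
#'   see [pupilcf()].
#' @return An `op_char` data frame with one row per rate: `rate` name,
#'   `estimate`, `n` (denominator), `se`.
#' @export
operating_characteristics <- function(spec, n_reps = 1, alpha = 0.01, m = 5,
                                      k = 4, method = "rank_sum",
                                      alternative = "two_sided",
                                      rest_pooling = "pooled") {
  stopifnot(inherits(spec, "cohort_spec"), n_reps >= 1)
  schedule <- build_schedule(spec$variant)
  task_sig <- logical(0); task_truth <- logical(0)
  subj_cf <- logical(0); subj_truth <- logical(0)
  for (rep in seq_len(n_reps)) {
    rspec <- spec
    rspec$params$seed <- derive_seed(spec$params$seed, 100000L + rep)
    cohort <- simulate_cohort(rspec, schedule)
    for (subj in cohort) {
      fit <- pupilcf(subj$recording, schedule, alpha = alpha, m = m, k = k,
                     method = method, alternative = alternative,
                     rest_pooling = rest_pooling)
      task_sig <- c(task_sig, fit$comparisons$significant_dilation)
      task_truth <- c(task_truth, rep(subj$responder, 5L))
      subj_cf <- c(subj_cf, fit$command_following)
      subj_truth <- c(subj_truth, subj$responder)
    }
  }
  rate_row <- function(name, x) {
    n <- length(x)
    p <- if (n) mean(x) else NA_real_
    data.frame(rate = name, estimate = p, n = n,
               se = if (n) sqrt(p * (1 - p) / n) else NA_real_)
  }
  out <- rbind(
    rate_row("task_false_positive", task_sig[!task_truth]),
    rate_row("task_true_positive", task_sig[task_truth]),
    rate_row("subject_false_positive", subj_cf[!subj_truth]),
    rate_row("subject_power", subj_cf[subj_truth])
  )
  structure(out, class = c("op_char", "data.frame"),
            n_reps = n_reps, alpha = alpha, m = m, k = k)
}
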