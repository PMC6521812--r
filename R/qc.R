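#' Baseline pupillary-function screen for one eye
#'
#' Carries the device's light-reflex summary values for one eye. Only the
#' Neurological Pupil index (NPi, a proprietary 0-5 sum score of light-reflex
#' integrity, consumed here as a given number) enters the inclusion rule; the
#' remaining fields are pass-through metadata.
#'
#' @param npi NPi score in \[0, 5\].
#' @param baseline_diameter_mm Pre-light-exposure pupil diameter (optional).
#' @param post_light_diameter_mm Diameter after light exposure (optional).
#' @param percent_change Percent diameter change (optional).
#' @param constriction_velocity,dilation_velocity Device velocities (optional).
#' @return An object of class `baseline_screen`.
#' @export
baseline_screen <- function(npi, baseline_diameter_mm = NA_real_,
                            post_light_diameter_mm = NA_real_,
                            percent_change = NA_real_,
                            constriction_velocity = NA_real_,
                            dilation_velocity = NA_real_) {
  if (!is.numeric(npi) || length(npi) != 1L || is.na(npi) ||
      npi < 0 || npi > 5)
    stop("`npi` must be a single number in [0, 5]", call. = FALSE)
  for (d in list(baseline_diameter_mm, post_light_diameter_mm)) {
    if (!is.na(d) && d <= 0)
      stop("diameters must be positive when present", call. = FALSE)
  }
  structure(list(npi = npi,
                 baseline_diameter_mm = baseline_diameter_mm,
                 post_light_diameter_mm = post_light_diameter_mm,
                 percent_change = percent_change,
                 constriction_velocity = constriction_velocity,
                 dilation_velocity = dilation_velocity),
            class = "baseline_screen")
}

#' Screen a participant for inclusion on baseline pupillary function
#'
#' A participant is included when both eyes have an NPi of at least 3
#' (physiological limits) and the inter-eye NPi difference is strictly below
#' 0.7. A difference of exactly 0.7 excludes. Failed rules are enumerated:
#' `"npi_below_3"` and/or `"inter_eye_diff"`.
#'
#' @param left,right `baseline_screen` objects (or bare NPi numbers) for the
#'   left and right eye.
#' @return A `qc_decision`: list with `include` (logical) and `reasons`
#'   (character vector, empty when included).
#' @examples
#' screen_participant(4.3, 4.3)$include        # TRUE
#' screen_participant(2.9, 4.0)$reasons        # both rules fail
#' @export
screen_participant <- function(left, right) {
  if (is.numeric(left)) left <- baseline_screen(left)
  if (is.numeric(right)) right <- baseline_screen(right)
  stopifnot(inherits(left, "baseline_screen"),
            inherits(right, "baseline_screen"))
  reasons <- character(0)
  if (left$npi < 3 || right$npi < 3) reasons <- c(reasons, "npi_below_3")
  if (abs(left$npi - right$npi) >= 0.7) reasons <- c(reasons, "inter_eye_diff")
  structure(list(include = length(reasons) == 0L, reasons = reasons),
            class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  if (x$include) cat("QC decision: include\n")
  else cat("QC decision: exclude (", paste(x$reasons, collapse = ", "), ")\n",
           sep = "")
  invisible(x)
}

#' Screen a cohort from a long-format screening table
#'
#' @param screens Data frame with one row per participant-eye and columns
#'   `subject_id`, `eye` (`"left"`/`"right"`), `npi`, and optionally
#'   `baseline_diameter_mm`.
#' @return Data frame with one row per subject: `subject_id`, `include`, and
#'   `reasons` (failed rules, `;`-separated, `""` when included).
#' @export
screen_cohort <- function(screens) {
  need <- c("subject_id", "eye", "npi")
  if (!all(need %in% names(screens)))
    stop("`screens` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(screens$subject_id)
  out <- lapply(ids, function(id) {
    rows <- screens[screens$subject_id == id, ]
    l <- rows[rows$eye == "left", ]
    r <- rows[rows$eye == "right", ]
    if (nrow(l) != 1L || nrow(r) != 1L)
      stop("subject ", id, ": need exactly one left and one right screen",
           call. = FALSE)
    d <- screen_participant(baseline_screen(l$npi), baseline_screen(r$npi))
    data.frame(subject_id = id, include = d$include,
               reasons = paste(d$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flag artifact samples in a recording
#'
#' Optional validity flagging for dropouts and implausible jumps: a valid
#' sample is marked invalid when its diameter falls below `min_diameter_mm`
#' or when it steps more than `max_step_mm` from the previous retained valid
#' sample. Diameter values are never altered and flagged samples are never
#' interpolated; downstream epoch statistics simply ignore invalid samples.
#' The pipeline leaves this off by default, mirroring an analysis of raw
#' traces with no artifact removal.
#'
#' The previous-valid-sample reference is maintained over retained samples
#' only, which makes the operation idempotent.
#'
#' @param recording A `pupil_recording`.
#' @param min_diameter_mm Minimum plausible diameter (mm).
#' @param max_step_mm Maximum plausible step between consecutive valid
#'   samples (mm).
#' @return The recording with updated validity flags.
#' @export
flag_artifacts <- function(recording, min_diameter_mm = 1, max_step_mm = 1) {
  stopifnot(inherits(recording, "pupil_recording"))
  if (min_diameter_mm <= 0 || max_step_mm <= 0)
    stop("thresholds must be positive", call. = FALSE)
  s <- recording$samples
  valid <- s$valid
  last <- NA_real_
  for (i in seq_len(nrow(s))) {
    if (!valid[i]) next
    d <- s$diameter_mm[i]
    if (d < min_diameter_mm || (!is.na(last) && abs(d - last) > max_step_mm)) {
      valid[i] <- FALSE
    } else {
      last <- d
    }
  }
  recording$samples$valid <- valid
  recording
}

#' Run-chart data for visual quality control
#'
#' Produces the plot-ready series for a time-ordered run chart of the raw
#' diameter trace with epoch shading: task epochs green, rest epochs yellow.
#' Invalid samples are rendered as gaps (`NA`), never interpolated.
#'
#' @param recording A non-empty `pupil_recording`.
#' @param schedule A `paradigm_schedule`.
#' @return A `run_chart` object: list with `time_s`, `diameter_mm` (NA at
#'   invalid samples), and `bands` (epoch shading with colors).
#' @export
run_chart <- function(recording, schedule) {
  stopifnot(inherits(recording, "pupil_recording"))
  if (nrow(recording$samples) == 0L)
    stop("empty recording: nothing to chart", call. = FALSE)
  s <- recording$samples
  d <- ifelse(s$valid, s$diameter_mm, NA_real_)
  bands <- data.frame(
    start_s = schedule$start_s, end_s = schedule$end_s,
    kind = schedule$kind, label = schedule$label,
    color = ifelse(schedule$kind == "task", "palegreen", "lightyellow"),
    stringsAsFactors = FALSE
  )
  structure(list(subject_id = recording$subject_id,
                 time_s = s$time_s, diameter_mm = d, bands = bands),
            class = "run_chart")
}

#' @param x A `run_chart`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @rdname run_chart
#' @export
plot.run_chart <- function(x, main = paste("Run chart:", x$subject_id), ...) {
  rng <- range(x$diameter_mm, na.rm = TRUE)
  graphics::plot(x$time_s, x$diameter_mm, type = "n",
                 xlab = "time (s)", ylab = "pupil diameter (mm)",
                 main = main, ...)
  graphics::rect(x$bands$start_s, rng[1] - 1, x$bands$end_s, rng[2] + 1,
                 col = grDevices::adjustcolor(x$bands$color, alpha.f = 0.5),
                 border = NA)
  graphics::lines(x$time_s, x$diameter_mm, lwd = 1)
  invisible(x)
}
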