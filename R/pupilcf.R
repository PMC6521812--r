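#' Detect command following from one pupil recording
#'
#' The central fitting function of the package. It runs the full per-subject
#' detection procedure: (optionally) flag artifact samples, segment the
#' recording into the paradigm's rest/task epochs, test each task epoch
#' against its flanking rest periods with a rank test under Bonferroni
#' correction, and apply the at-least-`k`-of-5 command-following rule.
#'
#' @param recording A `pupil_recording` covering the schedule span.
#' @param schedule A `paradigm_schedule`; defaults to the moderate variant
#'   (five ~30 s tasks with 30 s rests).
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.01).
#' @param m Bonferroni factor, the number of tasks (default 5).
#' @param k Significant dilations required for command following (default 4).
#' @param method,alternative,rest_pooling Test configuration; see
#'   [compare_task()].
#' @param artifact_flagging If `TRUE`, run [flag_artifacts()] before
#'   segmentation. Off by default: the reference analysis tests raw traces.
#' @param min_diameter_mm,max_step_mm Thresholds for [flag_artifacts()].
#' @return An object of class `pupilcf`: the subject decision
#'   (`command_following`, `n_significant`), the five-task comparison table
#'   (`comparisons`), and the inputs and resolved configuration, with
#'   `print()`, `summary()` and `plot()` methods.
#' @examples
#' sched <- build_schedule("moderate")
#' rec <- simulate_recording(sched, sim_params(seed = 7))$recording
#' fit <- pupilcf(rec, sched)
#' fit$command_following
#' @export
pupilcf <- function(recording, schedule = build_schedule("moderate"),
                    alpha = 0.01, m = 5, k = 4,
                    method = c("rank_sum", "signed_rank_truncated"),
                    alternative = c("two_sided", "greater"),
                    rest_pooling = c("pooled", "both"),
                    artifact_flagging = FALSE,
                    min_diameter_mm = 1, max_step_mm = 1) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  rest_pooling <- match.arg(rest_pooling)
  stopifnot(inherits(recording, "pupil_recording"))
  if (artifact_flagging)
    recording <- flag_artifacts(recording, min_diameter_mm, max_step_mm)

  epochs <- segment_recording(recording, schedule)
  task_pos <- which(schedule$kind == "task")
  comparisons <- lapply(task_pos, function(i) {
    compare_task(epochs[[i]], epochs[[i - 1L]], epochs[[i + 1L]],
                 alpha = alpha, m = m, rest_pooling = rest_pooling,
                 method = method, alternative = alternative)
  })
  res <- evaluate_subject(comparisons, k = k,
                          subject_id = recording$subject_id)
  structure(list(
    subject_id = res$subject_id,
    comparisons = res$comparisons,
    n_significant = res$n_significant,
    command_following = res$command_following,
    recording = recording, schedule = schedule,
    config = list(alpha = alpha, m = m, k = k, method = method,
                  alternative = alternative, rest_pooling = rest_pooling,
                  artifact_flagging = artifact_flagging,
                  min_diameter_mm = min_diameter_mm,
                  max_step_mm = max_step_mm)
  ), class = "pupilcf")
}

#' @export
print.pupilcf <- function(x, ...) {
  cat(sprintf("Command-following detection from pupillometry: subject %s\n",
              x$subject_id))
  cat(sprintf("  %d of 5 tasks with significant dilation (alpha = %g, Bonferroni m = %d)\n",
              x$n_significant, x$config$alpha, x$config$m))
  cat(sprintf("  Command following: %s (rule: >= %d of 5)\n",
              if (x$command_following) "DETECTED" else "not detected",
              x$config$k))
  invisible(x)
}

#' @export
summary.pupilcf <- function(object, ...) {
  structure(list(fit = object), class = "summary.pupilcf")
}

#' @export
print.summary.pupilcf <- function(x, ...) {
  f <- x$fit
  print(f)
  tab <- f$comparisons
  tab$median_task_mm <- round(tab$median_task_mm, 3)
  tab$median_rest_mm <- round(tab$median_rest_mm, 3)
  tab$p_raw <- signif(tab$p_raw, 3)
  tab$p_adj <- signif(tab$p_adj, 3)
  tab$label <- f$schedule$label[f$schedule$kind == "task"]
  cat("\nPer-task comparisons (task vs flanking rests):\n")
  print(tab, row.names = FALSE)
  cat(sprintf("\nTest: %s, %s, rest pooling '%s'\n",
              f$config$method, f$config$alternative, f$config$rest_pooling))
  invisible(x)
}

#' Plot a command-following fit as an annotated run chart
#'
#' Draws the diameter trace over epoch shading (task epochs green, rest
#' epochs yellow). With `annotate = TRUE` each task epoch is marked with a
#' check mark (significant dilation) or a division sign (no dilation /
#' not significant), the task and rest medians, and `#` where the adjusted
#' p-value is below 1e-4. Invalid samples appear as gaps.
#'
#' @param x A `pupilcf` object.
#' @param annotate Add per-task marks and medians (default `TRUE`).
#' @param main Title.
#' @param ... Passed to the underlying plot.
#' @export
plot.pupilcf <- function(x, annotate = TRUE,
                         main = paste("Subject", x$subject_id), ...) {
  rc <- run_chart(x$recording, x$schedule)
  plot(rc, main = main, ...)
  if (!annotate) return(invisible(x))
  tab <- x$comparisons
  tasks <- x$schedule[x$schedule$kind == "task", ]
  ytop <- max(rc$diameter_mm, na.rm = TRUE)
  for (i in seq_len(nrow(tab))) {
    mid <- (tasks$start_s[i] + tasks$end_s[i]) / 2
    mark <- if (tab$significant_dilation[i]) "✓" else "÷"
    if (tab$p_adj[i] < 1e-4) mark <- paste0(mark, " #")
    graphics::text(mid, ytop, mark, font = 2)
    graphics::text(mid, ytop - 0.06 * diff(range(rc$diameter_mm, na.rm = TRUE)),
                   sprintf("m=%.2f", tab$median_task_mm[i]), cex = 0.7)
  }
  graphics::mtext(sprintf("%d/5 significant dilations; command following %s",
                          x$n_significant,
                          if (x$command_following) "detected" else "not detected"),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}

#' Two-panel subject report figure
#'
#' Writes a figure with the raw trace (top) and the annotated run chart
#' (bottom) for one fitted subject, mirroring the raw/annotated presentation
#' convention of bedside pupillometry reports.
#'
#' @param fit A `pupilcf` object.
#' @param file Output PNG path.
#' @param width,height,res Device settings.
#' @return `file`, invisibly.
#' @export
report_subject <- function(fit, file, width = 1200, height = 800, res = 120) {
  stopifnot(inherits(fit, "pupilcf"))
  grDevices::png(file, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  s <- fit$recording$samples
  graphics::plot(s$time_s, ifelse(s$valid, s$diameter_mm, NA),
                 type = "l", xlab = "time (s)", ylab = "pupil diameter (mm)",
                 main = paste("Raw trace:", fit$subject_id))
  plot(fit, main = paste("Annotated:", fit$subject_id))
  invisible(file)
}
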