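#' Segment a recording into epoch sample sets
#'
#' Assigns every valid sample to exactly one schedule epoch using the
#' half-open convention `[start_s, end_s)` — a sample falling exactly on a
#' boundary belongs to the later epoch. Invalid samples are dropped. Samples
#' before the schedule start or at/after its end belong to no epoch. A
#' recording that ends before the schedule does raises a warning.
#'
#' @param recording A `pupil_recording`.
#' @param schedule A `paradigm_schedule`.
#' @return List (ordered as the schedule) of `epoch_samples`: each a list
#'   with `epoch` (one schedule row) and `diameters` (numeric vector of valid
#'   diameters in the epoch).
#' @export
segment_recording <- function(recording, schedule) {
  stopifnot(inherits(recording, "pupil_recording"))
  s <- recording$samples
  if (nrow(s) > 0L && max(s$time_s) < max(schedule$end_s) - 1)
    warning(sprintf(
      "recording ends at %.1f s but schedule spans %.1f s; trailing epochs are under-sampled",
      max(s$time_s), max(schedule$end_s)), call. = FALSE)
  v <- s[s$valid, , drop = FALSE]
  idx <- findInterval(v$time_s, schedule$start_s)          # half-open bins
  idx[v$time_s >= max(schedule$end_s)] <- 0L               # past the end
  lapply(seq_len(nrow(schedule)), function(i) {
    structure(list(epoch = schedule[i, , drop = FALSE],
                   diameters = v$diameter_mm[idx == i]),
              class = "epoch_samples")
  })
}

epoch_diameters <- function(e) {
  if (inherits(e, "epoch_samples")) e$diameters else as.numeric(e)
}

epoch_name <- function(e, fallback) {
  if (inherits(e, "epoch_samples"))
    sprintf("%s %d", e$epoch$kind, e$epoch$index)
  else fallback
}

#' Compare one task epoch against its flanking rest epochs
#'
#' The detection unit of the paradigm: the pupil diameters of one task epoch
#' are tested against the diameters of the rest periods immediately before
#' and after. In `"pooled"` mode (default) the two rest vectors are
#' concatenated and a single rank test is run; in `"both"` mode the task is
#' tested against each rest separately and the larger (less significant)
#' p-value is kept, so the task must beat both rests. The raw p-value is
#' Bonferroni-adjusted for the `m` tasks of the session, and a significant
#' dilation requires both `p_adj < alpha` and a task median strictly above
#' the pooled rest median.
#'
#' @param task,rest_before,rest_after `epoch_samples` (from
#'   [segment_recording()]) or bare numeric diameter vectors; each must hold
#'   at least 2 valid samples.
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @param m Number of comparisons for the Bonferroni correction (default 5).
#' @param rest_pooling `"pooled"` or `"both"`.
#' @param method,alternative Passed to [rank_test()].
#' @param task_index Task ordinal (1-5), taken from the epoch when available.
#' @return A `task_comparison`: list with `task_index`, `n_task`, `n_rest`,
#'   `median_task_mm`, `median_rest_mm`, `statistic`, `p_raw`, `p_adj`,
#'   `dilated`, `significant_dilation`.
#' @export
compare_task <- function(task, rest_before, rest_after, alpha = 0.01, m = 5,
                         rest_pooling = c("pooled", "both"),
                         method = c("rank_sum", "signed_rank_truncated"),
                         alternative = c("two_sided", "greater"),
                         task_index = NA_integer_) {
  rest_pooling <- match.arg(rest_pooling)
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (is.na(task_index) && inherits(task, "epoch_samples"))
    task_index <- task$epoch$index
  xs <- list(task = task, rest_before = rest_before, rest_after = rest_after)
  for (nm in names(xs)) {
    d <- epoch_diameters(xs[[nm]])
    if (length(d) < 2L)
      stop(sprintf("epoch '%s' has %d valid samples; need at least 2",
                   epoch_name(xs[[nm]], nm), length(d)), call. = FALSE)
  }
  x <- epoch_diameters(task)
  rb <- epoch_diameters(rest_before)
  ra <- epoch_diameters(rest_after)
  rest_all <- c(rb, ra)

  if (rest_pooling == "pooled") {
    rt <- rank_test(x, rest_all, method = method, alternative = alternative)
  } else {
    t1 <- rank_test(x, rb, method = method, alternative = alternative)
    t2 <- rank_test(x, ra, method = method, alternative = alternative)
    rt <- if (t1$p >= t2$p) t1 else t2
  }

  med_task <- stats::median(x)
  med_rest <- stats::median(rest_all)
  p_adj <- min(1, m * rt$p)
  dilated <- med_task > med_rest
  structure(list(
    task_index = as.integer(task_index),
    n_task = length(x), n_rest = length(rest_all),
    median_task_mm = med_task, median_rest_mm = med_rest,
    statistic = rt$statistic, p_raw = rt$p, p_adj = p_adj,
    dilated = dilated,
    significant_dilation = dilated && p_adj < alpha
  ), class = "task_comparison")
}

#' @export
as.data.frame.task_comparison <- function(x, ...) {
  data.frame(task_index = x$task_index, n_task = x$n_task, n_rest = x$n_rest,
             median_task_mm = x$median_task_mm,
             median_rest_mm = x$median_rest_mm,
             statistic = x$statistic, p_raw = x$p_raw, p_adj = x$p_adj,
             dilated = x$dilated,
             significant_dilation = x$significant_dilation)
}

#' @export
print.task_comparison <- function(x, ...) {
  cat(sprintf(
    "Task %d: median %.2f mm vs rest %.2f mm (n = %d/%d), p_adj = %.4g -> %s\n",
    x$task_index, x$median_task_mm, x$median_rest_mm, x$n_task, x$n_rest,
    x$p_adj,
    if (x$significant_dilation) "significant dilation"
    else if (x$dilated) "dilated, not significant" else "no dilation"))
  invisible(x)
}

#' Apply the command-following decision rule to five task comparisons
#'
#' A subject is classified as command-following when at least `k` of the five
#' mental-arithmetic tasks show a significant pupillary dilation (default
#' k = 4, i.e. 80%).
#'
#' @param comparisons List of exactly 5 `task_comparison` objects.
#' @param k Required number of significant dilations (default 4).
#' @param subject_id Subject label for the result.
#' @return A `subject_result`: list with `subject_id`, `comparisons` (5-row
#'   data frame), `n_significant`, `command_following`, `k`.
#' @export
evaluate_subject <- function(comparisons, k = 4, subject_id = "subject") {
  if (!is.list(comparisons) || length(comparisons) != 5L ||
      !all(vapply(comparisons, inherits, logical(1), "task_comparison")))
    stop("`comparisons` must be a list of exactly 5 task_comparison objects",
         call. = FALSE)
  tab <- do.call(rbind, lapply(comparisons, as.data.frame))
  n_sig <- sum(tab$significant_dilation)
  structure(list(subject_id = subject_id, comparisons = tab,
                 n_significant = n_sig,
                 command_following = n_sig >= k, k = k),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("Subject %s: %d/5 significant dilations -> command following %s (rule: >= %d)\n",
              x$subject_id, x$n_significant,
              if (x$command_following) "DETECTED" else "not detected", x$k))
  invisible(x)
}
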