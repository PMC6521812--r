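#' Arithmetic problem lists for the two paradigm variants
#'
#' @param variant `"moderate"` (2x2-digit multiplications) or `"simple"`
#'   (1x2-digit multiplications).
#' @return Character vector of five problem strings, in presentation order.
#' @export
paradigm_problems <- function(variant = c("moderate", "simple")) {
  variant <- match.arg(variant)
  x <- "×" # multiplication sign
  switch(variant,
    moderate = paste0(c("21 ", "33 ", "55 ", "43 ", "81 "), x,
                      c(" 22", " 32", " 54", " 44", " 82")),
    simple   = paste0(c("4 ", "8 ", "3 ", "6 ", "7 "), x,
                      c(" 46", " 32", " 67", " 37", " 43"))
  )
}

#' Build a mental-arithmetic paradigm schedule
#'
#' Constructs the alternating rest/task epoch layout of the paradigm: a rest
#' period, then five arithmetic task epochs each followed by a rest period,
#' so that every task has a rest period both before and after (6 rests, 5
#' tasks, 11 epochs in total). The moderate variant uses 30 s task and rest
#' epochs (330 s total); the simple variant uses 15 s epochs (165 s total).
#'
#' Epoch intervals are half-open `[start_s, end_s)`: a sample falling exactly
#' on a boundary belongs to the later epoch, so the epochs partition the
#' recording span with no gaps or overlaps.
#'
#' @param variant Paradigm difficulty variant, `"moderate"` or `"simple"`.
#' @param task_duration_s Task epoch length in seconds. Defaults to 30 for
#'   the moderate variant and 15 for the simple variant.
#' @param rest_duration_s Rest epoch length in seconds; same defaults.
#' @return A `paradigm_schedule`: a data frame with columns `kind`
#'   (`"rest"`/`"task"`), `index` (ordinal within kind), `start_s`, `end_s`,
#'   and `label` (the arithmetic problem for task epochs, `""` for rest),
#'   with the variant stored as an attribute.
#' @examples
#' sched <- build_schedule("moderate")
#' nrow(sched)            # 11 epochs
#' max(sched$end_s)       # 330 s
#' @export
build_schedule <- function(variant = c("moderate", "simple"),
                           task_duration_s = NULL, rest_duration_s = NULL) {
  variant <- match.arg(variant)
  default <- if (variant == "moderate") 30 else 15
  if (is.null(task_duration_s)) task_duration_s <- default
  if (is.null(rest_duration_s)) rest_duration_s <- default
  if (!is.numeric(task_duration_s) || length(task_duration_s) != 1L ||
      !is.finite(task_duration_s) || task_duration_s <= 0)
    stop("`task_duration_s` must be a single positive number", call. = FALSE)
  if (!is.numeric(rest_duration_s) || length(rest_duration_s) != 1L ||
      !is.finite(rest_duration_s) || rest_duration_s <= 0)
    stop("`rest_duration_s` must be a single positive number", call. = FALSE)

  labels <- paradigm_problems(variant)
  kind <- rep(c("rest", "task"), length.out = 11L)
  dur <- ifelse(kind == "task", task_duration_s, rest_duration_s)
  end <- cumsum(dur)
  start <- end - dur
  sched <- data.frame(
    kind = kind,
    index = stats::ave(seq_along(kind), kind, FUN = seq_along),
    start_s = start,
    end_s = end,
    label = "",
    stringsAsFactors = FALSE
  )
  sched$label[sched$kind == "task"] <- labels
  structure(sched, variant = variant,
            class = c("paradigm_schedule", "data.frame"))
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat(sprintf("Paradigm schedule (%s variant): %d epochs, %g s total\n",
              attr(x, "variant"), nrow(x), max(x$end_s)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

schedule_span <- function(schedule) max(schedule$end_s) - min(schedule$start_s)
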