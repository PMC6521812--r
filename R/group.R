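#' Summarize command-following outcomes for one group
#'
#' Aggregates subject-level results into the standard cohort table: the
#' distribution of subjects by number of significant dilations (0-5) and the
#' proportion passing the at-least-`k`-of-5 rule. By default each assessment
#' counts once; with `by = "subject"` repeated assessments of the same
#' subject are collapsed to one record that is successful if any of its
#' assessments was (used for patient-level narrative rates).
#'
#' @param results Either a list of `subject_result`/`pupilcf` objects, or an
#'   integer vector of per-assessment significant-dilation counts (0-5).
#' @param group_label Label for the group.
#' @param k Decision-rule threshold (default 4).
#' @param subject_ids Optional subject labels (recycled from the objects when
#'   `results` is a list); required for `by = "subject"` with a bare vector.
#' @param by `"assessment"` (default) or `"subject"`.
#' @return A `group_summary`: list with `group_label`, `n_assessments`,
#'   `n_success`, `proportion`, `percent` (integer, table style),
#'   `percent_1dp` (one decimal, narrative style), and `distribution` (named
#'   counts for 0-5 significant).
#' @examples
#' # healthy-control column: 2,2,0,2,13,1 subjects with 0..5 significant
#' g <- summarize_group(rep(0:5, c(2, 2, 0, 2, 13, 1)), "healthy")
#' g$percent  # 70
#' @export
summarize_group <- function(results, group_label = "group", k = 4,
                            subject_ids = NULL,
                            by = c("assessment", "subject")) {
  by <- match.arg(by)
  if (is.list(results)) {
    if (length(results) == 0L) stop("`results` is empty", call. = FALSE)
    n_sig <- vapply(results, function(r) as.integer(r$n_significant),
                    integer(1))
    if (is.null(subject_ids))
      subject_ids <- vapply(results, function(r) as.character(r$subject_id),
                            character(1))
  } else {
    n_sig <- as.integer(results)
    if (length(n_sig) == 0L) stop("`results` is empty", call. = FALSE)
  }
  if (any(is.na(n_sig)) || any(n_sig < 0L | n_sig > 5L))
    stop("significant-dilation counts must be integers in 0..5",
         call. = FALSE)

  if (by == "subject") {
    if (is.null(subject_ids))
      stop("`by = \"subject\"` needs `subject_ids`", call. = FALSE)
    # a subject is successful if any assessment passes; keep max count
    n_sig <- vapply(split(n_sig, subject_ids), max, integer(1))
  }

  success <- n_sig >= k
  dist <- table(factor(n_sig, levels = 0:5))
  n <- length(n_sig)
  prop <- sum(success) / n
  structure(list(group_label = group_label,
                 n_assessments = n, n_success = sum(success),
                 proportion = prop,
                 percent = round(100 * prop),
                 percent_1dp = round(100 * prop, 1),
                 distribution = as.integer(dist),
                 k = k, by = by),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group '%s' (%d %ss):\n", x$group_label, x$n_assessments,
              x$by))
  tab <- data.frame(n_significant = 0:5, count = x$distribution)
  print(tab, row.names = FALSE)
  cat(sprintf("Successful (>= %d of 5): %d/%d = %d%%\n",
              x$k, x$n_success, x$n_assessments, x$percent))
  invisible(x)
}

#' @export
as.data.frame.group_summary <- function(x, ...) {
  data.frame(group = x$group_label,
             stat = c(paste0(0:5, " significant"), "Successful"),
             value = c(x$distribution,
                       sprintf("%d%% (n = %d/%d)", x$percent, x$n_success,
                               x$n_assessments)),
             stringsAsFactors = FALSE)
}

#' Measurement-level dilation rate
#'
#' The proportion of individual task measurements (not subjects) in which a
#' pupillary dilation was observed, with the percentage rounded to at most 2
#' decimals for narrative reporting.
#'
#' @param n_dilations Number of measurements with dilation.
#' @param n_measurements Total number of measurements (> 0).
#' @return List with `n_dilations`, `n_measurements`, `proportion` (exact),
#'   and `percent` (rounded to 2 decimals).
#' @examples
#' measurement_rate(7, 15)$percent  # 46.67
#' @export
measurement_rate <- function(n_dilations, n_measurements) {
  if (!is.numeric(n_measurements) || length(n_measurements) != 1L ||
      n_measurements <= 0)
    stop("`n_measurements` must be a positive count", call. = FALSE)
  if (!is.numeric(n_dilations) || length(n_dilations) != 1L ||
      n_dilations < 0 || n_dilations > n_measurements)
    stop("`n_dilations` must lie in [0, n_measurements]", call. = FALSE)
  p <- n_dilations / n_measurements
  list(n_dilations = n_dilations, n_measurements = n_measurements,
       proportion = p, percent = round(100 * p, 2))
}

#' Risk ratio between two group success proportions
#'
#' Wald risk ratio on the log scale: `rr = (s1/n1) / (s2/n2)`, standard error
#' `se_log = sqrt(1/s1 - 1/n1 + 1/s2 - 1/n2)`, confidence bounds
#' `exp(log(rr) -/+ z * se_log)`, z-statistic `log(rr)/se_log`, and two-sided
#' normal p-value. No continuity correction: groups with zero successes are
#' rejected (an exact method would be needed there).
#'
#' @param s1,n1 Successes and total in group 1 (e.g. healthy controls).
#' @param s2,n2 Successes and total in group 2 (e.g. patients).
#' @param conf Confidence level (default 0.95).
#' @return An `rr_result`: list with `rr`, `se_log`, `ci_low`, `ci_high`,
#'   `z`, `p_two_sided`, `conf` and the input counts.
#' @examples
#' rr <- risk_ratio(14, 20, 17, 44)
#' round(c(rr$rr, rr$z, rr$ci_low), 2)  # 1.81 2.48 1.13
#' @export
risk_ratio <- function(s1, n1, s2, n2, conf = 0.95) {
  for (v in list(s1, n1, s2, n2))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("counts must be single non-negative numbers", call. = FALSE)
  if (s1 > n1 || s2 > n2)
    stop("successes cannot exceed totals", call. = FALSE)
  if (s1 == 0 || s2 == 0)
    stop("zero successes in a group: the Wald log-RR interval is undefined; use an exact method",
         call. = FALSE)
  if (!is.numeric(conf) || conf <= 0 || conf >= 1)
    stop("`conf` must be in (0, 1)", call. = FALSE)
  rr <- (s1 / n1) / (s2 / n2)
  se <- sqrt(1 / s1 - 1 / n1 + 1 / s2 - 1 / n2)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  z <- log(rr) / se
  structure(list(rr = rr, se_log = se,
                 ci_low = exp(log(rr) - zq * se),
                 ci_high = exp(log(rr) + zq * se),
                 z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
                 conf = conf, s1 = s1, n1 = n1, s2 = s2, n2 = n2),
            class = "rr_result")
}

#' @export
print.rr_result <- function(x, ...) {
  cat(sprintf(
    "Risk ratio %.2f, %d%% CI [%.2f-%.2f]; z = %.2f; p = %.3f  (%d/%d vs %d/%d)\n",
    x$rr, round(100 * x$conf), x$ci_low, x$ci_high, x$z, x$p_two_sided,
    x$s1, x$n1, x$s2, x$n2))
  invisible(x)
}
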