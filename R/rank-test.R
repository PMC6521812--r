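#' Rank test between a task sample and a rest sample
#'
#' Two flavours are offered. `rank_sum` is the Mann-Whitney/Wilcoxon rank-sum
#' test on the two (unpaired, possibly unequal-length) sample vectors, with
#' mid-ranks for ties: the p-value is exact when both groups are tie-free and
#' the smaller group has at most 8 observations (or `exact = TRUE` is
#' forced), otherwise a normal approximation with tie-corrected variance and
#' no continuity correction is used. `signed_rank_truncated` mirrors the
#' paired Wilcoxon signed-rank test on samples of unequal length: the longer
#' vector is trimmed symmetrically to the shorter length, the trimmed vectors
#' are paired in time order, zero differences are dropped, and the p-value is
#' exact for at most 12 non-zero tie-free differences.
#'
#' If all paired differences are zero the test is degenerate; by convention
#' the p-value is 1 and the result carries `degenerate = TRUE`.
#'
#' @param x,y Non-empty numeric sample vectors (task and rest diameters).
#' @param method `"rank_sum"` (default) or `"signed_rank_truncated"`.
#' @param alternative `"two_sided"` (default) or `"greater"` (x stochastically
#'   larger than y).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact null
#'   distribution; `NULL` applies the size/tie rule above.
#' @return List with `statistic` (W for rank_sum, V for signed rank), `p`,
#'   `method`, `exact` (whether the exact distribution was used), and
#'   `degenerate`.
#' @examples
#' rank_test(c(4, 5, 6), c(1, 2, 3), alternative = "greater")$p  # 1/20
#' @export
rank_test <- function(x, y, method = c("rank_sum", "signed_rank_truncated"),
                      alternative = c("two_sided", "greater"), exact = NULL) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  alt <- if (alternative == "two_sided") "two.sided" else "greater"
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L || anyNA(x) || anyNA(y))
    stop("`x` and `y` must be non-empty and free of missing values",
         call. = FALSE)

  if (method == "rank_sum") {
    ties <- anyDuplicated(c(x, y)) > 0L
    if (is.null(exact)) exact <- !ties && min(length(x), length(y)) <= 8L
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alt, exact = exact,
                         correct = FALSE))
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                method = method, exact = exact && !ties, degenerate = FALSE))
  }

  # signed_rank_truncated: symmetric trim to equal length, pair, drop zeros
  n <- min(length(x), length(y))
  x <- trim_center(x, n)
  y <- trim_center(y, n)
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(statistic = NA_real_, p = 1, method = method,
                exact = FALSE, degenerate = TRUE))
  ties <- anyDuplicated(abs(d)) > 0L
  if (is.null(exact)) exact <- !ties && length(d) <= 12L
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = alt, exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = method, exact = exact && !ties, degenerate = FALSE)
}

# keep the central n elements, dropping floor/ceil of the excess at the ends
trim_center <- function(v, n) {
  excess <- length(v) - n
  if (excess == 0L) return(v)
  from <- floor(excess / 2) + 1L
  v[from:(from + n - 1L)]
}
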