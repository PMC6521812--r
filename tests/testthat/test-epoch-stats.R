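test_that("segmentation assigns valid samples to half-open epochs", {
  sched <- build_schedule("moderate")
  rec <- simulate_recording(sched, sim_params(seed = 2,
                                              blink_rate_per_min = 0))$recording
  segs <- segment_recording(rec, sched)
  expect_length(segs, 11L)
  expect_true(all(vapply(segs, function(e) length(e$diameters), 0L) == 900L))

  # a sample exactly on a boundary belongs to the later epoch
  rec2 <- make_recording(rep(4, 5), fs = 1)       # times 0..4
  sched2 <- build_schedule("simple", task_duration_s = 2, rest_duration_s = 2)
  expect_warning(segs2 <- segment_recording(rec2, sched2), "under-sampled")
  expect_length(segs2[[1]]$diameters, 2L)         # t = 0, 1
  expect_length(segs2[[2]]$diameters, 2L)         # t = 2, 3 (2 is boundary)

  # all-invalid recording yields 11 empty epochs
  rec3 <- pupil_recording(seq(0, 329.9, by = 1), rep(NA_real_, 330))
  segs3 <- segment_recording(rec3, sched)
  expect_true(all(vapply(segs3, function(e) length(e$diameters), 0L) == 0L))
})

test_that("rank_test reproduces hand-enumerated exact p-values", {
  rt <- rank_test(c(4, 5, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(rt$p, 1 / 20)                      # 1 of C(6,3) assignments
  expect_true(rt$exact)

  # 5 pairs, all differences positive: one-sided signed-rank p = 1/32
  x <- c(5.1, 5.2, 5.3, 5.4, 5.5); y <- c(4.1, 4.3, 4.25, 4.45, 4.0)
  rt <- rank_test(x, y, method = "signed_rank_truncated",
                  alternative = "greater")
  expect_equal(rt$p, 1 / 2^5)

  # identical samples: two-sided p = 1
  x <- c(1.5, 2.5, 3.5, 4.5)
  expect_equal(rank_test(x, x)$p, 1, tolerance = 1e-12)

  expect_error(rank_test(numeric(0), 1:3), "non-empty")
})

test_that("exact branches match brute-force enumeration across sizes", {
  set.seed(101)
  for (n1 in c(2L, 4L, 6L, 8L)) {
    for (n2 in c(2L, 5L, 8L)) {
      s <- tie_free_pair(n1, n2)
      for (alt in c("two_sided", "greater")) {
        expect_equal(rank_test(s$x, s$y, alternative = alt)$p,
                     oracle_rank_sum(s$x, s$y, alt),
                     info = sprintf("rank_sum n1=%d n2=%d %s", n1, n2, alt))
      }
    }
  }
  for (n in c(3L, 6L, 9L, 12L)) {
    s <- tie_free_pair(n, n)
    for (alt in c("two_sided", "greater")) {
      expect_equal(
        rank_test(s$x, s$y, method = "signed_rank_truncated",
                  alternative = alt)$p,
        oracle_signed_rank(s$x - s$y, alt),
        info = sprintf("signed_rank n=%d %s", n, alt))
    }
  }
})

test_that("signed-rank trimming and degenerate cases behave as specified", {
  # longer vector trimmed symmetrically before pairing
  x <- c(9, 5.1, 5.25, 5.3, 9)      # central trim keeps 5.1, 5.25, 5.3
  y <- c(4.0, 4.12, 4.21)
  rt <- rank_test(x, y, method = "signed_rank_truncated",
                  alternative = "greater")
  expect_equal(rt$p, 1 / 8)          # 3 positive differences
  # all-zero differences: p = 1 by convention, flagged
  rt <- rank_test(c(4, 4, 4), c(4, 4, 4), method = "signed_rank_truncated")
  expect_true(rt$degenerate)
  expect_equal(rt$p, 1)
})

test_that("compare_task combines test, direction and Bonferroni threshold", {
  set.seed(77)
  task <- rnorm(400, 5.1, 0.05)
  rest1 <- rnorm(400, 4.6, 0.05); rest2 <- rnorm(400, 4.6, 0.05)
  cmp <- compare_task(task, rest1, rest2, task_index = 1L)
  expect_true(cmp$dilated)
  expect_true(cmp$significant_dilation)
  expect_lt(cmp$p_adj, 1e-4)
  expect_equal(cmp$n_rest, 800L)
  expect_true(cmp$p_adj >= cmp$p_raw)

  # identical constant epochs: no dilation, p = 1
  cmp <- compare_task(rep(4, 10), rep(4, 10), rep(4, 10), task_index = 2L)
  expect_false(cmp$dilated)
  expect_false(cmp$significant_dilation)

  # dilated but adjusted p above alpha: not significant
  set.seed(78)
  task <- rnorm(12, 4.06, 0.1); rest <- rnorm(12, 4.0, 0.1)
  cmp <- compare_task(task, rest[1:6], rest[7:12])
  if (cmp$dilated && cmp$p_adj >= 0.01) expect_false(cmp$significant_dilation)
  expect_identical(cmp$significant_dilation,
                   cmp$dilated && cmp$p_adj < 0.01)

  expect_error(compare_task(numeric(0), rest[1:6], rest[7:12]),
               "at least 2")
})

test_that("'both' rest pooling requires beating the worse rest", {
  set.seed(12)
  task <- rnorm(200, 4.6, 0.05)
  low <- rnorm(200, 4.0, 0.05)      # easily beaten
  high <- rnorm(200, 4.6, 0.05)     # same distribution as task
  pooled <- compare_task(task, low, high, rest_pooling = "pooled")
  both <- compare_task(task, low, high, rest_pooling = "both")
  expect_gte(both$p_raw, pooled$p_raw)
  expect_false(both$significant_dilation)
})

test_that("adding a positive shift to the task never hurts detection", {
  set.seed(31)
  for (i in 1:10) {
    task <- rnorm(50, 4, 0.2); rest1 <- rnorm(50, 4, 0.2)
    rest2 <- rnorm(50, 4, 0.2)
    base <- compare_task(task, rest1, rest2, alternative = "greater")
    shifted <- compare_task(task + 0.5, rest1, rest2,
                            alternative = "greater")
    expect_true(shifted$dilated >= base$dilated)
    expect_lte(shifted$p_raw, base$p_raw)
  }
})

test_that("subject rule counts significant dilations against threshold k", {
  mk <- function(sig) {
    structure(list(task_index = 1L, n_task = 10L, n_rest = 20L,
                   median_task_mm = 5, median_rest_mm = 4.5,
                   statistic = 1, p_raw = if (sig) 1e-6 else 0.5,
                   p_adj = if (sig) 5e-6 else 1, dilated = TRUE,
                   significant_dilation = sig),
              class = "task_comparison")
  }
  comps <- lapply(c(TRUE, TRUE, TRUE, TRUE, FALSE), mk)
  expect_true(evaluate_subject(comps)$command_following)
  expect_false(evaluate_subject(comps, k = 5)$command_following)
  comps3 <- lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE), mk)
  expect_false(evaluate_subject(comps3)$command_following)
  zero <- lapply(rep(FALSE, 5), mk)
  r <- evaluate_subject(zero)
  expect_false(r$command_following)
  expect_equal(r$n_significant, 0L)
  expect_error(evaluate_subject(comps[1:4]), "exactly 5")

  # permutation invariance
  set.seed(4)
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  base <- evaluate_subject(lapply(flags, mk))
  for (i in 1:5) {
    perm <- evaluate_subject(lapply(sample(flags), mk))
    expect_identical(perm$command_following, base$command_following)
    expect_identical(perm$n_significant, base$n_significant)
  }
})

test_that("significant_dilation implies dilated across simulated fits", {
  sched <- build_schedule("simple")
  for (seed in 1:6) {
    p <- sim_params(seed = seed, dilation_amplitude_mm = runif(1, 0, 0.4),
                    noise_sd_mm = 0.1, sampling_rate_hz = 10)
    fit <- pupilcf(simulate_recording(sched, p)$recording, sched)
    expect_true(all(!fit$comparisons$significant_dilation |
                      fit$comparisons$dilated))
    expect_identical(fit$command_following, fit$n_significant >= 4)
  }
})
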