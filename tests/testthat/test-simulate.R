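test_that("generator is deterministic and leaves the caller's RNG alone", {
  sched <- build_schedule("moderate")
  p <- sim_params(seed = 99)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- simulate_recording(sched, p)
  mid <- runif(1)
  b <- simulate_recording(sched, p)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_equal(mid, before)   # RNG stream undisturbed by the generator
})

test_that("degenerate parameters give a constant baseline trace", {
  sched <- build_schedule("simple")
  p <- sim_params(dilation_amplitude_mm = 0, noise_sd_mm = 0,
                  drift_amplitude_mm = 0, blink_rate_per_min = 0, seed = 1)
  rec <- simulate_recording(sched, p)$recording
  expect_true(all(rec$samples$diameter_mm == p$baseline_mm))
  expect_true(all(rec$samples$valid))
  expect_false(simulate_recording(sched, p)$responder)
})

test_that("a responder's task medians exceed flanking rest medians", {
  sched <- build_schedule("moderate")
  p <- sim_params(dilation_amplitude_mm = 0.5, noise_sd_mm = 0.05,
                  tau_s = 2, seed = 14)
  sim <- simulate_recording(sched, p)
  expect_true(sim$responder)
  fit <- pupilcf(sim$recording, sched)
  expect_true(all(fit$comparisons$dilated))
  expect_equal(fit$n_significant, 5L)
})

test_that("recording morphology matches the paradigm", {
  sched <- build_schedule("moderate")
  p <- sim_params(seed = 21, blink_rate_per_min = 6)
  rec <- simulate_recording(sched, p)$recording
  expect_equal(nrow(rec$samples), 330 * 30)
  expect_lt(recording_duration(rec), 330)
  expect_true(any(!rec$samples$valid))         # blinks present
  runs <- rle(rec$samples$valid)
  expect_true(all(runs$lengths[!runs$values] <=
                    ceiling(p$blink_duration_s * p$sampling_rate_hz) + 1))
  expect_error(simulate_recording(sched[0, ], p), "empty schedule")
  expect_error(sim_params(baseline_mm = 0.5), "\\(1, 9\\)")
  expect_error(sim_params(tau_s = 0), "positive")
})

test_that("cohort truth labels follow the responder fraction and seed rule", {
  p <- sim_params(seed = 5, sampling_rate_hz = 5)
  all_null <- simulate_cohort(cohort_spec(6, 0, params = p, variant = "simple"))
  expect_true(all(!vapply(all_null, `[[`, logical(1), "responder")))
  all_resp <- simulate_cohort(cohort_spec(6, 1, params = p, variant = "simple"))
  expect_true(all(vapply(all_resp, `[[`, logical(1), "responder")))

  a <- simulate_cohort(cohort_spec(8, 0.5, params = p, variant = "simple"))
  b <- simulate_cohort(cohort_spec(8, 0.5, params = p, variant = "simple"))
  expect_identical(vapply(a, `[[`, logical(1), "responder"),
                   vapply(b, `[[`, logical(1), "responder"))
  expect_identical(a[[3]]$recording$samples, b[[3]]$recording$samples)
  # extending the cohort never reshuffles earlier subjects
  big <- simulate_cohort(cohort_spec(12, 0.5, params = p, variant = "simple"))
  expect_identical(big[[3]]$recording$samples, a[[3]]$recording$samples)
})

test_that("task-rest median difference recovers the dilation amplitude", {
  # long epochs so the first-order kernel sits near its asymptotes
  sched <- build_schedule("moderate", task_duration_s = 60,
                          rest_duration_s = 60)
  a <- 0.4
  p <- sim_params(dilation_amplitude_mm = a, tau_s = 2, noise_sd_mm = 0.05,
                  drift_amplitude_mm = 0, blink_rate_per_min = 0, seed = 6)
  fit <- pupilcf(simulate_recording(sched, p)$recording, sched)
  est <- mean(fit$comparisons$median_task_mm - fit$comparisons$median_rest_mm)
  expect_equal(est, a, tolerance = 0.1)
})

test_that("detection power is non-decreasing in dilation amplitude", {
  p0 <- sim_params(noise_sd_mm = 0.08, drift_amplitude_mm = 0,
                   sampling_rate_hz = 10, seed = 77)
  rates <- vapply(c(0, 0.15, 0.5), function(a) {
    spec <- cohort_spec(12, 1, amplitude_mm = max(a, 1e-9), params = p0,
                        variant = "simple")
    oc <- operating_characteristics(spec)
    oc$estimate[oc$rate == "subject_power"]
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 1)
})

test_that("operating characteristics report rates with MC standard errors", {
  p <- sim_params(sampling_rate_hz = 10, drift_amplitude_mm = 0, seed = 10)
  oc <- operating_characteristics(cohort_spec(6, 0.5, params = p,
                                              variant = "simple"),
                                  n_reps = 2)
  expect_s3_class(oc, "op_char")
  expect_setequal(oc$rate, c("task_false_positive", "task_true_positive",
                             "subject_false_positive", "subject_power"))
  expect_equal(sum(oc$n[oc$rate %in% c("subject_false_positive",
                                       "subject_power")]), 12)
  ok <- !is.na(oc$estimate)
  expect_true(all(oc$estimate[ok] >= 0 & oc$estimate[ok] <= 1))
  expect_true(all(oc$se[ok] >= 0))
  # n_reps = 1 with a single subject gives degenerate {0,1} rates
  oc1 <- operating_characteristics(cohort_spec(1, 1, params = p,
                                               variant = "simple"))
  expect_true(oc1$estimate[oc1$rate == "subject_power"] %in% c(0, 1))
})
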