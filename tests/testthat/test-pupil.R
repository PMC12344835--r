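ramp_trace <- function(n = 3000, dt = 1) {
  t <- seq(0, by = dt, length.out = n)
  data.frame(time_ms = t, pupil_mm = 3 + 0.0002 * t, valid = TRUE)
}

test_that("interpolation fills runs strictly shorter than the gap limit", {
  # 1 ms sampling so run durations are exact milliseconds
  tr <- ramp_trace()
  tr$valid[501:596] <- FALSE            # 96 ms run inside a linear ramp
  out <- interpolate_gaps(tr)
  expect_true(all(out$valid))
  expect_equal(out$pupil_mm, ramp_trace()$pupil_mm)   # analytically exact
  expect_true(all(out$interpolated[501:596]))

  tr2 <- ramp_trace()
  tr2$valid[501:600] <- FALSE           # exactly 100 ms: untouched
  out2 <- interpolate_gaps(tr2)
  expect_false(any(out2$valid[501:600]))

  tr3 <- ramp_trace()
  tr3$valid[1:50] <- FALSE              # touches the trace start: untouched
  out3 <- interpolate_gaps(tr3)
  expect_false(any(out3$valid[1:50]))

  clean <- interpolate_gaps(ramp_trace())
  expect_equal(clean$pupil_mm, ramp_trace()$pupil_mm)
  # idempotence
  expect_equal(interpolate_gaps(out2)$valid, out2$valid)
  expect_equal(interpolate_gaps(out2)$pupil_mm, out2$pupil_mm)
})

test_that("interpolation equals a brute-force reference on random traces", {
  set.seed(50)
  for (i in 1:20) {
    tr <- random_trace(n = 400, rate = 120, p_invalid_run = 0.2)
    tr <- tr[c("time_ms", "pupil_mm", "valid")]
    ref <- interpolate_oracle(tr)
    out <- interpolate_gaps(tr)
    expect_equal(out$pupil_mm[out$valid], ref$pupil_mm[ref$valid])
    expect_equal(out$valid, ref$valid)
  }
})

test_that("moving median removes spikes and matches the windowed reference", {
  t <- seq(0, 1000, by = 10)
  const <- data.frame(time_ms = t, pupil_mm = 3, valid = TRUE)
  out <- pupil_median_filter(interpolate_gaps(const))
  expect_true(all(out$pupil_mm == 3))

  spike <- const
  spike$pupil_mm[50] <- 4
  outs <- pupil_median_filter(interpolate_gaps(spike))
  expect_equal(outs$pupil_mm[50], 3)

  set.seed(51)
  for (i in 1:20) {
    tr <- random_trace(n = 300, rate = 120, p_invalid_run = 0.15)
    tr <- interpolate_gaps(tr[c("time_ms", "pupil_mm", "valid")])
    out <- pupil_median_filter(tr)
    expect_equal(out$pupil_mm, median_filter_oracle(tr))
  }
})

test_that("median filter is near-idempotent on monotone traces", {
  # away from the truncated end windows the filter is a fixed point
  tr <- interpolate_gaps(ramp_trace(n = 500, dt = 8))
  once <- pupil_median_filter(tr)
  twice <- pupil_median_filter(once)
  interior <- 12:489
  expect_lt(max(abs(twice$pupil_mm[interior] - once$pupil_mm[interior])),
            1e-9)
})

test_that("amplitude is baseline-subtracted and shift-invariant", {
  sched <- data.frame(trial_id = 1L, peripheral_onset_ms = 1500L)
  t <- seq(0, 3100, by = 10)
  tr <- data.frame(time_ms = t, pupil_mm = 3, valid = TRUE)
  a <- process_pupil(tr, sched)
  expect_equal(a$pupil_baseline_mm, 3)
  expect_equal(a$pupil_amplitude_mm, 0)

  tr2 <- tr
  tr2$pupil_mm <- tr$pupil_mm + 0.5
  a2 <- process_pupil(tr2, sched)
  expect_equal(a2$pupil_baseline_mm, a$pupil_baseline_mm + 0.5)
  expect_equal(a2$pupil_amplitude_mm, a$pupil_amplitude_mm)

  # window entirely outside the trace
  short <- data.frame(time_ms = seq(0, 400, 10), pupil_mm = 3, valid = TRUE)
  expect_error(process_pupil(short, sched), "window error")
})

test_that("amplitudes with under 30% valid samples are unusable", {
  sched <- data.frame(trial_id = 1L, peripheral_onset_ms = 1500L)
  t <- seq(0, 3100, by = 10)
  tr <- data.frame(time_ms = t, pupil_mm = 3, valid = TRUE)
  win <- (t >= 500 & t < 834) | (t >= 1500 & t < 3000)
  kill <- which(win)
  kill <- kill[seq_len(ceiling(0.75 * length(kill)))]
  tr$valid[kill] <- FALSE
  tr$pupil_mm[kill] <- NA
  a <- process_pupil(tr, sched)
  expect_false(a$pupil_valid)
  expect_true(is.na(a$pupil_amplitude_mm))
})

test_that("the pipeline refuses out-of-order stage calls", {
  t <- seq(0, 3100, by = 10)
  tr <- data.frame(time_ms = t, pupil_mm = 3, valid = TRUE)
  sched <- data.frame(trial_id = 1L, peripheral_onset_ms = 1500L)
  expect_error(pupil_median_filter(tr), "interpolate_gaps")
  expect_error(compute_amplitude(tr, sched), "pipeline order")
  expect_error(compute_amplitude(interpolate_gaps(tr), sched),
               "pipeline order")
})

test_that("the MAD rule removes exactly the hand-flagged outliers", {
  amp <- data.frame(participant_id = "P1",
                    pupil_amplitude_mm = c(1.0, 1.1, 0.9, 1.05, 5.0))
  res <- mad_outlier_filter(amp)
  expect_equal(res$data$mad_outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$kept$pupil_amplitude_mm, c(1.0, 1.1, 0.9, 1.05))

  same <- data.frame(participant_id = "P1",
                     pupil_amplitude_mm = rep(1, 6))
  expect_warning(res2 <- mad_outlier_filter(same), "degenerate")
  expect_false(any(res2$data$mad_outlier))

  few <- data.frame(participant_id = "P1", pupil_amplitude_mm = c(1, 2, 9))
  expect_warning(res3 <- mad_outlier_filter(few), "fewer than 4")
  expect_false(any(res3$data$mad_outlier))
})

test_that("MAD removal fraction on Gaussian data matches normal theory", {
  set.seed(52)
  amp <- data.frame(participant_id = "P1",
                    pupil_amplitude_mm = rnorm(10000, 0.1, 0.2))
  res <- suppressWarnings(mad_outlier_filter(amp))
  frac <- mean(res$data$mad_outlier)
  # 2 * (1 - pnorm(3)) = 0.27% with the 1.4826 consistency constant
  expect_gt(frac, 0.0005)
  expect_lt(frac, 0.006)
  expect_equal(res$data$mad_outlier,
               !mad_keep_oracle(amp$pupil_amplitude_mm))
})
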