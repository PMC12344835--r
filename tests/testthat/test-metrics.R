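test_that("gaze-shift extraction reads out entry latency and exclusions", {
  tr <- synthetic_shift_trial(entry_ms = 250)
  out <- extract_gaze_shift(tr$samples, tr$schedule)
  expect_true(out$shifted)
  expect_equal(out$latency_ms, 250)
  expect_equal(out$exclusion, "none")

  early <- synthetic_shift_trial(entry_ms = 95)
  out_e <- extract_gaze_shift(early$samples, early$schedule)
  expect_equal(out_e$exclusion, "anticipatory")
  expect_true(is.na(out_e$latency_ms))
  expect_equal(out_e$latency_raw_ms, 95)

  late <- synthetic_shift_trial(entry_ms = 1005)
  out_l <- extract_gaze_shift(late$samples, late$schedule)
  expect_equal(out_l$exclusion, "improbable")
  expect_equal(out_l$latency_raw_ms, 1005)
})

test_that("no-shift, wrong-side, off-central and no-data trials are flagged", {
  ns <- synthetic_shift_trial(enter = FALSE)
  out <- extract_gaze_shift(ns$samples, ns$schedule)
  expect_false(out$shifted)
  expect_equal(out$exclusion, "none")

  wrong <- synthetic_shift_trial(entry_ms = 300, side = "left")
  out_w <- extract_gaze_shift(wrong$samples, wrong$schedule)
  expect_true(out_w$shifted)
  expect_true(out_w$wrong_side)
  expect_true(is.na(out_w$latency_ms))

  off <- synthetic_shift_trial(entry_ms = 300)
  pre <- off$samples$time_ms >= off$schedule$peripheral_onset_ms - 100 &
    off$samples$time_ms < off$schedule$peripheral_onset_ms
  off$samples$x_deg[pre] <- 10                       # parked on the target
  out_o <- extract_gaze_shift(off$samples, off$schedule)
  expect_equal(out_o$exclusion, "not_on_central")

  nodata <- synthetic_shift_trial(entry_ms = 300)
  win <- nodata$samples$time_ms >= nodata$schedule$peripheral_onset_ms &
    nodata$samples$time_ms < nodata$schedule$peripheral_offset_ms
  kill <- which(win)[seq_len(ceiling(0.6 * sum(win)))]
  nodata$samples$valid[kill] <- FALSE
  out_n <- extract_gaze_shift(nodata$samples, nodata$schedule)
  expect_equal(out_n$exclusion, "no_data")
})

test_that("latency exclusion boundaries are strict", {
  outcomes <- data.frame(participant_id = "P1",
                         latency_raw_ms = c(95, 100, 500, 1000, 1001),
                         latency_ms = c(95, 100, 500, 1000, 1001),
                         shifted = TRUE, exclusion = "none")
  res <- apply_latency_exclusions(outcomes)
  expect_equal(sort(res$kept$latency_ms), c(100, 500, 1000))
  expect_equal(res$outcomes$exclusion,
               c("anticipatory", "none", "none", "none", "improbable"))
  expect_equal(sum(res$tally$n[res$tally$reason == "anticipatory"]), 1L)

  empty <- apply_latency_exclusions(outcomes[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(sum(empty$tally$n), 0L)

  mid <- apply_latency_exclusions(transform(outcomes, latency_raw_ms = 500,
                                            latency_ms = 500))
  expect_equal(nrow(mid$kept), 5L)
})

test_that("participants need four valid trials in every condition", {
  mk <- function(pid, n_gap, n_os, n_oc) {
    data.frame(participant_id = pid,
               condition = rep(c("gap", "overlap_silent", "overlap_cued"),
                               c(n_gap, n_os, n_oc)),
               shifted = TRUE, exclusion = "none",
               latency_ms = 300)
  }
  outcomes <- rbind(mk("P1", 3, 10, 10), mk("P2", 4, 4, 4))
  res <- min_valid_trials_filter(outcomes, 4, "latency")
  expect_equal(res$retained, "P2")
  expect_false(res$report$retained[res$report$participant_id == "P1"])
  # a participant with no trials at all is removed
  outcomes$participant_id <- factor(outcomes$participant_id,
                                    levels = c("P1", "P2", "P3"))
  res2 <- min_valid_trials_filter(outcomes, 4, "latency")
  expect_false("P3" %in% res2$retained)
})

test_that("no-shift percentages use non-excluded trials as the denominator", {
  outcomes <- data.frame(
    participant_id = "P1",
    condition = c(rep("gap", 10), rep("overlap_silent", 8),
                  rep("overlap_cued", 3)),
    shifted = c(rep(c(FALSE, TRUE), c(2, 8)), rep(TRUE, 8), rep(TRUE, 3)),
    exclusion = c(rep("none", 18), rep("anticipatory", 3)))
  s <- summarize_noshift(outcomes)
  expect_equal(s$noshift_pct[s$condition == "gap"], 20)
  expect_equal(s$noshift_pct[s$condition == "overlap_silent"], 0)
  expect_true(is.na(s$noshift_pct[s$condition == "overlap_cued"]))
})

test_that("the trial partition holds on simulated cohorts", {
  truth <- simulation_truth(dropout_rate = 0.08)
  co <- simulate_cohort(c(WS = 1, TD = 1), truth, seed = 21)
  out <- compute_trial_outcomes(co$gaze, co$schedules)
  for (pid in unique(out$participant_id)) {
    d <- out[out$participant_id == pid, ]
    n_shift <- sum(d$shifted & d$exclusion == "none", na.rm = TRUE)
    n_noshift <- sum(!d$shifted & d$exclusion == "none", na.rm = TRUE)
    n_excl <- sum(d$exclusion != "none")
    expect_equal(n_shift + n_noshift + n_excl, nrow(d))
  }
})

test_that("simulated no-shift percentage matches the binomial expectation", {
  truth <- simulation_truth(groups = "TD", noshift_rate = c(
    gap = 0.25, overlap_silent = 0.25, overlap_cued = 0.25),
    group_noshift_logit_shift = c(TD = 0), group_latency_ratio = c(TD = 1),
    noshift_slope_per_mm = 0, participant_noshift_sd = 0)
  tt <- simulate_trial_table(c(TD = 180), truth, seed = 31)
  s <- summarize_noshift(tt)
  grand <- mean(s$noshift_pct, na.rm = TRUE)
  expect_lt(abs(grand - 25), 3 * 100 * sqrt(0.25 * 0.75 / nrow(tt)))
})
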