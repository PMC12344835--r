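test_that("default schedule reproduces the session design and is deterministic", {
  s <- generate_schedule(task_config(), seed = 1)
  expect_equal(nrow(s), 58L)
  expect_equal(as.vector(table(s$condition)[c("gap", "overlap_silent",
                                              "overlap_cued")]),
               c(21L, 18L, 19L))
  expect_equal(nrow(validate_schedule(s)), 0L)
  expect_identical(generate_schedule(task_config(), seed = 7),
                   generate_schedule(task_config(), seed = 7))
  empty <- generate_schedule(task_config(n_gap = 0, n_overlap_silent = 0,
                                         n_overlap_cued = 0), seed = 1)
  expect_equal(nrow(empty), 0L)
})

test_that("timing draws respect every design interval across seeds", {
  cfg <- task_config()
  gap_durs <- central_durs <- leads <- integer(0)
  for (seed in 1:50) {
    s <- generate_schedule(cfg, seed)
    expect_equal(as.vector(table(s$condition)[c("gap", "overlap_silent",
                                                "overlap_cued")]),
                 c(21L, 18L, 19L))
    g <- s$condition == "gap"
    gd <- s$peripheral_onset_ms[g] - s$central_offset_ms[g]
    expect_true(all(gd >= 120 & gd <= 200))
    cd <- ifelse(g, s$central_offset_ms, s$peripheral_onset_ms)
    expect_true(all(cd >= 800 & cd <= 1700))
    expect_true(all(s$peripheral_offset_ms - s$peripheral_onset_ms == 1000))
    cued <- s$condition == "overlap_cued"
    ld <- s$peripheral_onset_ms[cued] - s$cue_onset_ms[cued]
    expect_true(all(ld >= 0 & ld <= 500))
    # side balance within rounding, no runs longer than 3
    expect_lte(abs(sum(s$target_side == "left") -
                     sum(s$target_side == "right")), 1L)
    expect_lte(max(rle(s$target_side)$lengths), 3L)
    gap_durs <- c(gap_durs, gd)
    central_durs <- c(central_durs, cd)
    leads <- c(leads, ld)
  }
  # uniform sampling should cover most of each interval; the wider intervals
  # need more schedules for full coverage
  for (seed in 51:300) {
    s <- generate_schedule(cfg, seed)
    g <- s$condition == "gap"
    gap_durs <- c(gap_durs, s$peripheral_onset_ms[g] - s$central_offset_ms[g])
    central_durs <- c(central_durs,
                      ifelse(g, s$central_offset_ms, s$peripheral_onset_ms))
    cued <- s$condition == "overlap_cued"
    leads <- c(leads, s$peripheral_onset_ms[cued] - s$cue_onset_ms[cued])
  }
  expect_gte(length(unique(gap_durs)) / length(120:200), 0.9)
  expect_gte(length(unique(leads)) / length(0:500), 0.9)
  expect_gte(length(unique(central_durs)) / length(800:1700), 0.9)
})

test_that("validate_schedule names the violated rule and trial", {
  s <- generate_schedule(task_config(), seed = 3)
  g <- which(s$condition == "gap")[1]
  s$peripheral_onset_ms[g] <- s$central_offset_ms[g] + 250L
  s$peripheral_offset_ms[g] <- s$peripheral_onset_ms[g] + 1000L
  v <- validate_schedule(s)
  expect_true(any(v$trial_id == s$trial_id[g] & v$rule == "gap_duration"))
  expect_match(v$detail[v$rule == "gap_duration"][1], "120, 200")

  s2 <- generate_schedule(task_config(), seed = 3)
  cued <- which(s2$condition == "overlap_cued")[1]
  s2$cue_onset_ms[cued] <- s2$peripheral_onset_ms[cued] - 600L
  v2 <- validate_schedule(s2)
  expect_true(any(v2$trial_id == s2$trial_id[cued] & v2$rule == "cue_lead"))
  expect_match(v2$detail[v2$rule == "cue_lead"][1], "0, 500")
})

test_that("schedules round-trip losslessly through JSON", {
  s <- generate_schedule(task_config(), seed = 11)
  path <- tempfile(fileext = ".json")
  write_schedule_json(s, path)
  s2 <- read_schedule_json(path)
  expect_equal(as.data.frame(s), as.data.frame(s2))
})

test_that("degenerate configuration is rejected", {
  expect_error(task_config(gap_duration_range_ms = c(300, 200)),
               "configuration error")
  expect_error(task_config(peripheral_duration_ms = -5),
               "configuration error")
  expect_error(aoi_set(left = aoi_rect(-2, 0, 6, 6)), "overlap")
})
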