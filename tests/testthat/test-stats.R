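balanced_cells <- function() {
  # 2 groups x 3 conditions, 8 participants per group, 2 trials per cell,
  # deterministic cell means plus tiny within-cell jitter
  grid <- expand.grid(participant = 1:8, rep = 1:2,
                      condition = c("gap", "overlap_silent", "overlap_cued"),
                      group = c("A", "B"), stringsAsFactors = FALSE)
  base <- c(gap = 5.6, overlap_silent = 5.8, overlap_cued = 5.9)
  shift <- c(A = 0, B = 0.2)
  grid$participant_id <- paste0(grid$group, grid$participant)
  grid$latency_ms <- exp(base[grid$condition] + shift[grid$group] +
                           rep(c(-0.01, 0.01), each = 1)[grid$rep])
  grid
}

test_that("with no participant variance the fit reproduces OLS cell means", {
  d <- balanced_cells()
  m <- suppressWarnings(fit_latency_lmm(d))
  mm <- marginal_means_and_contrasts(m, "by_condition_within_group")$means
  ols <- aggregate(log(latency_ms) ~ condition + group, d, mean)
  got <- mm$emmean[match(paste(ols$condition, ols$group),
                         paste(mm$condition, mm$group))]
  expect_equal(got, ols$`log(latency_ms)`, tolerance = 1e-8)
})

test_that("Bonferroni adjustment multiplies by the family size", {
  d <- balanced_cells()
  set.seed(60)
  d$latency_ms <- d$latency_ms * exp(rnorm(nrow(d), 0, 0.2))
  m <- suppressWarnings(fit_latency_lmm(d))
  cc <- marginal_means_and_contrasts(m, "by_condition_within_group")
  raw <- 2 * pt(-abs(cc$contrasts$t), cc$contrasts$df)
  expect_equal(cc$contrasts$p_adjusted,
               pmin(1, raw * cc$contrasts$family_size), tolerance = 1e-6)
  expect_equal(cc$contrasts$family_size, rep(3L, nrow(cc$contrasts)))
  # log-scale / ratio consistency
  expect_equal(cc$contrasts$ratio, exp(cc$contrasts$estimate))
  # estimable functions: each contrast is a difference of two marginal means
  mm <- cc$means
  for (i in seq_len(nrow(cc$contrasts))) {
    parts <- strsplit(cc$contrasts$label[i], " \\| ")[[1]]
    lv <- strsplit(parts[1], " - ")[[1]]
    g <- parts[2]
    expect_equal(cc$contrasts$estimate[i],
                 mm$emmean[mm$condition == lv[1] & mm$group == g] -
                   mm$emmean[mm$condition == lv[2] & mm$group == g],
                 tolerance = 1e-8)
  }
})

test_that("identical cells give zero contrasts and unit ratios", {
  d <- balanced_cells()
  d$latency_ms[d$condition == "overlap_silent"] <-
    d$latency_ms[d$condition == "gap"]
  m <- suppressWarnings(fit_latency_lmm(d))
  cc <- marginal_means_and_contrasts(m, "overall")$contrasts
  i <- grep("gap - overlap_silent", cc$label)
  expect_equal(cc$estimate[i], 0, tolerance = 1e-8)
  expect_equal(cc$ratio[i], 1, tolerance = 1e-8)
})

test_that("contract violations are rejected with informative errors", {
  d <- balanced_cells()
  expect_error(fit_latency_lmm(d[d$condition != "gap" | d$group != "A", ]),
               "singular-design error.*gap")
  m1 <- suppressWarnings(fit_latency_lmm(d[d$group == "A", ]))
  expect_error(marginal_means_and_contrasts(m1, "by_group_within_condition"),
               "contract error")
  expect_error(contrast_of_contrasts(m1), "contract error")
  expect_error(fit_pupil_lmm(data.frame(condition = "gap",
                                        pupil_amplitude_mm = 1)),
               "contract error")
  single <- data.frame(participant_id = "P1", group = "A",
                       condition = rep(c("gap", "overlap_silent",
                                         "overlap_cued"), each = 5),
                       latency_ms = 300)
  w <- capture_warnings(fit_latency_lmm(single))
  expect_true(any(grepl("degenerate", w)))
  expect_true(any(grepl("zero residual", w)))
})

test_that("the all-shift no-shift model estimates zero everywhere", {
  d <- balanced_cells()
  d$shifted <- TRUE
  m <- suppressWarnings(fit_noshift_lmm(d))
  mm <- marginal_means_and_contrasts(m, "by_condition_within_group")$means
  expect_true(all(abs(mm$emmean) < 1e-8))
})

test_that("no-shift cell means recover the generating probabilities", {
  truth <- simulation_truth(
    groups = "TD", group_latency_ratio = c(TD = 1),
    noshift_rate = c(gap = 0.20, overlap_silent = 0.25, overlap_cued = 0.30),
    group_noshift_logit_shift = c(TD = 0), noshift_slope_per_mm = 0,
    participant_noshift_sd = 0)
  tt <- simulate_trial_table(c(TD = 60), truth, seed = 61)
  m <- fit_noshift_lmm(tt)
  mm <- marginal_means_and_contrasts(m, "overall")$means
  want <- c(gap = 20, overlap_silent = 25, overlap_cued = 30)
  for (cond in names(want)) {
    n_cell <- sum(tt$condition == cond & tt$exclusion == "none")
    se <- 100 * sqrt(0.25 / n_cell)
    expect_lt(abs(mm$emmean[mm$condition == cond] - want[[cond]]), 3.5 * se)
  }
})

test_that("a cue effect present in one group shows up as its contrast-of-contrasts", {
  truth <- simulation_truth(
    groups = c("A", "B"),
    latency_median_ms = c(gap = 280, overlap_silent = 320,
                          overlap_cued = 320 * exp(-0.08)),
    group_latency_ratio = c(A = 1, B = 1),
    group_noshift_logit_shift = c(A = 0, B = 0),
    noshift_rate = c(gap = 0.05, overlap_silent = 0.05, overlap_cued = 0.05))
  # group B has no cue effect: equal silent/cued medians
  tt_a <- simulate_trial_table(c(A = 150), truth, seed = 62)
  truth_b <- truth
  truth_b$grid$latency_meanlog[truth_b$grid$condition == "overlap_cued"] <-
    log(320)
  tt_b <- simulate_trial_table(c(B = 150), truth_b, seed = 63)
  tt_b <- tt_b[tt_b$group == "B", ]
  m <- fit_latency_lmm(rbind(tt_a[tt_a$group == "A", ], tt_b))
  coc <- contrast_of_contrasts(m)$contrasts
  i <- grep("overlap_silent - overlap_cued", coc$label)
  expect_lt(abs(coc$estimate[i] - 0.08), 0.02)
})

test_that("GLMM odds ratios behave under null, separation and degeneracy", {
  truth0 <- simulation_truth(groups = "TD", group_latency_ratio = c(TD = 1),
                             group_noshift_logit_shift = c(TD = 0),
                             noshift_slope_per_mm = 0)
  tt <- simulate_trial_table(c(TD = 40), truth0, seed = 64)
  or <- fit_glmm_noshift_on_pupil(tt)
  expect_lt(abs(log(or$OR)), 3 * or$SE_log_odds)
  expect_equal(or$p_adjusted, min(1, or$p * 1))

  none <- tt[tt$condition == "overlap_cued", ]
  none$shifted <- TRUE
  expect_warning(or2 <- fit_glmm_noshift_on_pupil(none), "separation")
  expect_true(is.na(or2$OR))

  flat <- tt
  flat$pupil_amplitude_mm <- ave(flat$pupil_amplitude_mm,
                                 flat$participant_id)[1] * 0 + 0.1
  expect_error(fit_glmm_noshift_on_pupil(flat), "rank-deficiency")
})
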