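#' Ground-truth generating model for synthetic gap-overlap sessions
#'
#' Defines every parameter of the synthetic-session generator: per
#' group-by-condition lognormal gaze-shift latency distributions, a
#' trial-level logistic no-shift model coupled to the trial's true phasic
#' pupil amplitude, a gamma-shaped pupil impulse response, participant-level
#' random effects, sample dropout, and measurement noise. The defaults mirror
#' the published effect structure of the paradigm: overlap trials ~20% slower
#' than gap trials, a further latency cost on cued trials, developmentally
#' delayed groups ~25% slower than typically developed adults, no-shift rates
#' in the 3-45% range, and a cue-evoked pupil dilation of a few hundredths of
#' a millimetre.
#'
#' Latencies are generated as
#' `log L = latency_meanlog(group, condition) + u_i + e`, with participant
#' intercept `u_i ~ N(0, participant_sdlog^2)` and `e ~ N(0, latency_sdlog^2)`.
#' The no-shift probability of a trial is
#' `logit p = noshift_intercept(group, condition) + v_i + slope * (a - mean_a)`
#' where `a` is the trial's true phasic amplitude, so arousal and
#' disengagement failures are coupled at the trial level. The pupil trace is
#' `baseline_i + a * k(t - t_lock) + drift + noise` with `k` a peak-normalized
#' gamma kernel (`(t/tp)^s exp(s (1 - t/tp))`) time-locked to the cue on
#' cued trials and to target onset otherwise.
#'
#' @param groups character vector of group labels.
#' @param latency_median_ms named per-condition median latency (ms) for the
#'   reference group (ratio 1).
#' @param group_latency_ratio named multiplicative latency ratio per group.
#' @param latency_sdlog trial-level lognormal sd (log-ms).
#' @param participant_sdlog between-participant sd of the latency intercept
#'   (log-ms).
#' @param noshift_rate named per-condition no-shift probability at the cell's
#'   mean amplitude for a group with logit shift 0.
#' @param group_noshift_logit_shift named additive logit shift per group.
#' @param noshift_slope_per_mm logit change per mm of true phasic amplitude.
#' @param participant_noshift_sd between-participant sd on the no-shift logit.
#' @param pupil_baseline_mm,pupil_baseline_sd_mm tonic pupil level (mm) and
#'   its between-participant sd.
#' @param phasic_amplitude_mm named per-condition mean of the true phasic
#'   peak amplitude (mm).
#' @param group_amplitude_shift_mm named additive per-group shift of the
#'   cued-condition amplitude (mm).
#' @param amplitude_sd_mm trial-level sd of the true phasic amplitude (mm).
#' @param participant_amplitude_sd_mm between-participant sd of the phasic
#'   amplitude (mm).
#' @param amplitude_noise_sd_mm measurement noise added to the amplitude in
#'   the trial-level generator (mm).
#' @param kernel_latency_ms,kernel_shape pupil impulse-response
#'   latency-to-peak (ms) and shape.
#' @param dropout_rate expected fraction of invalid samples, in `[0, 1)`.
#' @param dropout_runlength_ms mean length (ms) of a missing run (geometric
#'   run lengths, uniformly placed).
#' @param sampling_rate_hz 120 or 1200.
#' @param gaze_noise_sd_deg,pupil_noise_sd_mm per-sample measurement noise.
#' @param drift_sd_mm amplitude (mm) of a slow sinusoidal pupil drift.
#' @param saccade_speed_deg_s constant saccade transit speed.
#' @return A list of class `simulation_truth` with a `grid` data frame of
#'   per-cell parameters.
#' @export
simulation_truth <- function(groups = c("WS", "ID", "TD", "TD_infant"),
                             latency_median_ms = c(gap = 270,
                                                   overlap_silent = 320,
                                                   overlap_cued = 335),
                             group_latency_ratio = c(WS = 1.25, ID = 1.25,
                                                     TD = 1, TD_infant = 0.95),
                             latency_sdlog = 0.25,
                             participant_sdlog = 0.10,
                             noshift_rate = c(gap = 0.15,
                                              overlap_silent = 0.20,
                                              overlap_cued = 0.25),
                             group_noshift_logit_shift = c(WS = 0, ID = 0.7,
                                                           TD = -1.5,
                                                           TD_infant = 0),
                             noshift_slope_per_mm = log(5),
                             participant_noshift_sd = 0.5,
                             pupil_baseline_mm = 3.2,
                             pupil_baseline_sd_mm = 0.45,
                             phasic_amplitude_mm = c(gap = 0.03,
                                                     overlap_silent = 0.03,
                                                     overlap_cued = 0.09),
                             group_amplitude_shift_mm = NULL,
                             amplitude_sd_mm = 0.15,
                             participant_amplitude_sd_mm = 0.03,
                             amplitude_noise_sd_mm = 0.05,
                             kernel_latency_ms = 930,
                             kernel_shape = 10.1,
                             dropout_rate = 0.05,
                             dropout_runlength_ms = 60,
                             sampling_rate_hz = 120,
                             gaze_noise_sd_deg = 0.3,
                             pupil_noise_sd_mm = 0.01,
                             drift_sd_mm = 0.02,
                             saccade_speed_deg_s = 300) {
  if (!sampling_rate_hz %in% c(120, 1200))
    stop_config("sampling_rate_hz must be 120 or 1200")
  if (latency_sdlog <= 0) stop_config("latency_sdlog must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate must lie in [0, 1)")
  if (is.null(group_amplitude_shift_mm))
    group_amplitude_shift_mm <- setNames(rep(0, length(groups)), groups)
  pick <- function(v, keys, what) {
    if (is.null(names(v))) v <- setNames(rep_len(v, length(keys)), keys)
    if (!all(keys %in% names(v)))
      stop_config(what, " must name every level: ",
                  paste(setdiff(keys, names(v)), collapse = ", "))
    v[keys]
  }
  latency_median_ms <- pick(latency_median_ms, CONDITIONS, "latency_median_ms")
  noshift_rate <- pick(noshift_rate, CONDITIONS, "noshift_rate")
  phasic_amplitude_mm <- pick(phasic_amplitude_mm, CONDITIONS,
                              "phasic_amplitude_mm")
  group_latency_ratio <- pick(group_latency_ratio, groups,
                              "group_latency_ratio")
  group_noshift_logit_shift <- pick(group_noshift_logit_shift, groups,
                                    "group_noshift_logit_shift")
  group_amplitude_shift_mm <- pick(group_amplitude_shift_mm, groups,
                                   "group_amplitude_shift_mm")
  grid <- expand.grid(group = groups, condition = CONDITIONS,
                      stringsAsFactors = FALSE)
  grid$latency_meanlog <- log(latency_median_ms[grid$condition]) +
    log(group_latency_ratio[grid$group])
  grid$amp_mean_mm <- phasic_amplitude_mm[grid$condition] +
    ifelse(grid$condition == "overlap_cued",
           group_amplitude_shift_mm[grid$group], 0)
  grid$noshift_intercept <- qlogis(noshift_rate[grid$condition]) +
    group_noshift_logit_shift[grid$group]
  truth <- list(groups = groups, grid = grid,
                latency_sdlog = latency_sdlog,
                participant_sdlog = participant_sdlog,
                noshift_slope_per_mm = noshift_slope_per_mm,
                participant_noshift_sd = participant_noshift_sd,
                pupil_baseline_mm = pupil_baseline_mm,
                pupil_baseline_sd_mm = pupil_baseline_sd_mm,
                amplitude_sd_mm = amplitude_sd_mm,
                participant_amplitude_sd_mm = participant_amplitude_sd_mm,
                amplitude_noise_sd_mm = amplitude_noise_sd_mm,
                kernel_latency_ms = kernel_latency_ms,
                kernel_shape = kernel_shape,
                dropout_rate = dropout_rate,
                dropout_runlength_ms = dropout_runlength_ms,
                sampling_rate_hz = sampling_rate_hz,
                gaze_noise_sd_deg = gaze_noise_sd_deg,
                pupil_noise_sd_mm = pupil_noise_sd_mm,
                drift_sd_mm = drift_sd_mm,
                saccade_speed_deg_s = saccade_speed_deg_s)
  class(truth) <- "simulation_truth"
  truth
}

truth_cell <- function(truth, group, condition) {
  g <- truth$grid
  row <- g[g$group == group & g$condition == condition, ]
  if (nrow(row) != 1L)
    stop_config("no ground-truth cell for group '", group,
                "', condition '", condition, "'")
  row
}

#' Peak-normalized gamma pupil impulse response
#'
#' `k(t) = (t / tp)^s * exp(s * (1 - t / tp))` for `t > 0`, zero otherwise;
#' the peak value 1 occurs at `t = tp`, so a phasic amplitude in mm scales
#' the kernel to its peak increment.
#'
#' @param t_ms time since the locking event (ms); vectorized.
#' @param latency_ms latency-to-peak `tp` (ms).
#' @param shape shape parameter `s`.
#' @return Kernel values in `[0, 1]`.
#' @export
pupil_kernel <- function(t_ms, latency_ms = 930, shape = 10.1) {
  ifelse(t_ms > 0,
         (t_ms / latency_ms)^shape * exp(shape * (1 - t_ms / latency_ms)),
         0)
}

#' Draw participant-level random effects
#'
#' @param truth a [simulation_truth()].
#' @param group group label.
#' @param participant_id identifier to attach.
#' @return A list with the participant's latency intercept (log-ms), no-shift
#'   logit intercept, and tonic pupil baseline (mm).
#' @export
draw_participant <- function(truth, group, participant_id = "P01") {
  if (!group %in% truth$groups) stop_config("unknown group '", group, "'")
  list(participant_id = participant_id, group = group,
       u_latency = rnorm(1, 0, truth$participant_sdlog),
       u_noshift = rnorm(1, 0, truth$participant_noshift_sd),
       u_amplitude = rnorm(1, 0, truth$participant_amplitude_sd_mm),
       pupil_baseline_mm = truth$pupil_baseline_mm +
         rnorm(1, 0, truth$pupil_baseline_sd_mm))
}

# Uniformly placed geometric missing runs hitting the stationary dropout rate.
dropout_mask <- function(n, dropout_rate, runlength_ms, dt) {
  if (dropout_rate <= 0 || n == 0L) return(rep(FALSE, n))
  m <- max(1, runlength_ms / dt)             # mean run length in samples
  lambda <- -log(1 - dropout_rate) / m       # run starts per sample
  k <- rpois(1, lambda * n)
  bad <- rep(FALSE, n)
  if (k > 0) {
    starts <- sample.int(n, k, replace = TRUE)
    lens <- rgeom(k, prob = min(1, 1 / m)) + 1L
    for (j in seq_len(k)) {
      idx <- starts[j]:min(n, starts[j] + lens[j] - 1L)
      bad[idx] <- TRUE
    }
  }
  bad
}

#' Simulate one gap-overlap trial
#'
#' Generates the gaze and pupil sample stream for one scheduled trial under
#' the ground-truth model, together with the trial's generating record. Gaze
#' fixates the central AOI, then (on shift trials) transits to the target AOI
#' at constant saccade speed, timed so that it crosses the target-AOI
#' boundary exactly at `peripheral_onset + latency`; the drawn latency is
#' therefore the AOI-entry latency that downstream extraction recovers. The
#' trace starts early enough to cover the pupil baseline window and runs
#' 100 ms past the peripheral offset.
#'
#' @param schedule_row one row of a `trial_schedule`.
#' @param truth a [simulation_truth()].
#' @param participant a list from [draw_participant()].
#' @param seed integer seed for the trial's stream. Trial-level quantities
#'   (latency, shift flag, amplitude) are drawn before any rate-dependent
#'   noise, so they are identical across sampling rates under the same seed.
#' @param aois an [aoi_set()] giving the target geometry.
#' @return `list(samples, truth)`: `samples` is a data frame with `time_ms`,
#'   `x_deg`, `y_deg`, `pupil_mm`, `valid`; `truth` is a one-row data frame
#'   with the drawn latency, shift flag, true phasic amplitude, and baseline.
#' @export
simulate_trial <- function(schedule_row, truth, participant, seed,
                           aois = aoi_set()) {
  if (!truth$sampling_rate_hz %in% c(120, 1200))
    stop_config("sampling_rate_hz must be 120 or 1200")
  cell <- truth_cell(truth, participant$group, schedule_row$condition)
  per_on <- schedule_row$peripheral_onset_ms
  per_off <- schedule_row$peripheral_offset_ms
  dt <- 1000 / truth$sampling_rate_hz
  t0 <- min(0, per_on - 1000 - dt)
  times <- seq(t0, per_off + 100, by = dt)
  n <- length(times)
  with_seed(seed, {
    # trial-level draws, fixed order, before any rate-dependent draw
    latency <- exp(cell$latency_meanlog + participant$u_latency +
                     rnorm(1, 0, truth$latency_sdlog))
    amp_true <- cell$amp_mean_mm + participant$u_amplitude +
      rnorm(1, 0, truth$amplitude_sd_mm)
    p_noshift <- plogis(cell$noshift_intercept + participant$u_noshift +
                          truth$noshift_slope_per_mm *
                          (amp_true - cell$amp_mean_mm))
    shifted <- runif(1) >= p_noshift
    drift_phase <- runif(1, 0, 2 * pi)
    # gaze path
    x <- rep(0, n)
    if (shifted) {
      tgt <- aois[[schedule_row$target_side]]
      edge <- abs(tgt[["x"]]) - tgt[["width"]] / 2
      entry_t <- per_on + latency
      start_t <- entry_t - edge / truth$saccade_speed_deg_s * 1000
      moved <- pmax(0, (times - start_t) / 1000 * truth$saccade_speed_deg_s)
      x <- sign(tgt[["x"]]) * pmin(abs(tgt[["x"]]), moved)
    }
    y <- rep(0, n)
    # pupil path
    t_lock <- if (!is.na(schedule_row$cue_onset_ms))
      schedule_row$cue_onset_ms else per_on
    pupil <- participant$pupil_baseline_mm +
      amp_true * pupil_kernel(times - t_lock, truth$kernel_latency_ms,
                              truth$kernel_shape) +
      truth$drift_sd_mm * sin(2 * pi * (times - t0) / 4000 + drift_phase)
    # rate-dependent draws: dropout then measurement noise
    bad <- dropout_mask(n, truth$dropout_rate, truth$dropout_runlength_ms, dt)
    if (truth$gaze_noise_sd_deg > 0) {
      x <- x + rnorm(n, 0, truth$gaze_noise_sd_deg)
      y <- y + rnorm(n, 0, truth$gaze_noise_sd_deg)
    }
    if (truth$pupil_noise_sd_mm > 0)
      pupil <- pupil + rnorm(n, 0, truth$pupil_noise_sd_mm)
    x[bad] <- NA_real_; y[bad] <- NA_real_; pupil[bad] <- NA_real_
    samples <- data.frame(time_ms = times, x_deg = x, y_deg = y,
                          pupil_mm = pupil, valid = !bad)
    rec <- data.frame(trial_id = schedule_row$trial_id,
                      condition = schedule_row$condition,
                      target_side = schedule_row$target_side,
                      latency_ms = latency, shifted = shifted,
                      amp_true_mm = amp_true,
                      p_noshift = p_noshift,
                      pupil_baseline_mm = participant$pupil_baseline_mm,
                      stringsAsFactors = FALSE)
    list(samples = samples, truth = rec)
  })
}

#' Simulate a whole cohort of gap-overlap sessions
#'
#' Draws independent participants per group (each with their own randomized
#' schedule and random effects) and simulates every trial, returning the
#' stacked gaze table, schedules, participant records, and the per-trial
#' ground-truth table. One global seed hierarchically spawns per-participant
#' and per-trial sub-streams, so output is fully reproducible and the
#' trial-level ground truth is invariant to the sampling rate.
#'
#' @param n_per_group named integer vector, e.g. `c(WS = 5, TD = 5)`.
#' @param truth a [simulation_truth()].
#' @param seed global integer seed.
#' @param config a [task_config()] for the per-participant schedules.
#' @param aois an [aoi_set()].
#' @return A list with `gaze` (one row per sample, keyed by participant and
#'   trial), `schedules`, `participants`, and `truth_table`.
#' @export
simulate_cohort <- function(n_per_group, truth, seed = 1L,
                            config = task_config(), aois = aoi_set()) {
  stopifnot(!is.null(names(n_per_group)), all(n_per_group >= 1L))
  if (!all(names(n_per_group) %in% truth$groups))
    stop_config("n_per_group names must be simulation groups")
  plan <- data.frame(group = rep(names(n_per_group), n_per_group),
                     stringsAsFactors = FALSE)
  plan$participant_id <- sprintf("%s_%02d", plan$group,
                                 unlist(lapply(n_per_group, seq_len)))
  pseeds <- spawn_seeds(seed, nrow(plan))
  gaze <- vector("list", nrow(plan))
  truths <- vector("list", nrow(plan))
  scheds <- vector("list", nrow(plan))
  parts <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    n_tr <- config$n_gap + config$n_overlap_silent + config$n_overlap_cued
    ss <- spawn_seeds(pseeds[i], 2L + n_tr)
    schedule <- generate_schedule(config, seed = ss[1])
    part <- with_seed(ss[2], draw_participant(truth, plan$group[i],
                                              plan$participant_id[i]))
    trial_out <- lapply(seq_len(nrow(schedule)), function(k) {
      simulate_trial(schedule[k, ], truth, part, seed = ss[2L + k],
                     aois = aois)
    })
    gz <- data.table::rbindlist(lapply(trial_out, function(o) {
      s <- o$samples
      s$trial_id <- o$truth$trial_id
      s
    }))
    data.table::set(gz, j = "participant_id", value = plan$participant_id[i])
    data.table::set(gz, j = "group", value = plan$group[i])
    gaze[[i]] <- gz
    tt <- data.table::rbindlist(lapply(trial_out, `[[`, "truth"))
    data.table::set(tt, j = "participant_id", value = plan$participant_id[i])
    data.table::set(tt, j = "group", value = plan$group[i])
    truths[[i]] <- tt
    schedule$participant_id <- plan$participant_id[i]
    scheds[[i]] <- schedule
    parts[[i]] <- data.frame(participant_id = plan$participant_id[i],
                             group = plan$group[i],
                             sampling_rate_hz = truth$sampling_rate_hz,
                             u_latency = part$u_latency,
                             u_noshift = part$u_noshift,
                             pupil_baseline_mm = part$pupil_baseline_mm,
                             stringsAsFactors = FALSE)
  }
  gaze <- as.data.frame(data.table::rbindlist(gaze))
  cols <- c("participant_id", "group", "trial_id", "time_ms", "x_deg",
            "y_deg", "pupil_mm", "valid")
  gaze <- gaze[cols]
  list(gaze = gaze,
       schedules = as.data.frame(data.table::rbindlist(scheds)),
       participants = do.call(rbind, parts),
       truth_table = as.data.frame(data.table::rbindlist(truths)))
}

#' Simulate a cohort directly at the trial level
#'
#' Generates per-trial outcomes (latency, shift flag, measured pupil
#' amplitude) from the same generating model as [simulate_cohort()] but
#' without constructing sample streams. This is the generator used for
#' statistical parameter-recovery and calibration studies, where hundreds of
#' replicate cohorts are fitted; the sample-level and trial-level generators
#' share the identical trial-level model.
#'
#' @inheritParams simulate_cohort
#' @return A trial-outcome `data.frame` with columns `participant_id`,
#'   `group`, `trial_id`, `condition`, `shifted`, `latency_ms` (AOI-entry
#'   latency, `NA` on no-shift trials), `exclusion` (anticipatory/improbable
#'   labels applied to out-of-range latencies), `pupil_amplitude_mm`
#'   (measured amplitude = true + measurement noise), `amp_true_mm`,
#'   `pupil_valid`.
#' @export
simulate_trial_table <- function(n_per_group, truth, seed = 1L,
                                 config = task_config()) {
  stopifnot(!is.null(names(n_per_group)), all(n_per_group >= 1L))
  plan <- data.frame(group = rep(names(n_per_group), n_per_group),
                     stringsAsFactors = FALSE)
  plan$participant_id <- sprintf("%s_%02d", plan$group,
                                 unlist(lapply(n_per_group, seq_len)))
  pseeds <- spawn_seeds(seed, nrow(plan))
  conds <- rep(CONDITIONS,
               c(config$n_gap, config$n_overlap_silent, config$n_overlap_cued))
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    out[[i]] <- with_seed(pseeds[i], {
      part <- draw_participant(truth, plan$group[i], plan$participant_id[i])
      condition <- sample(conds)
      cell <- truth$grid[match(paste(plan$group[i], condition),
                               paste(truth$grid$group, truth$grid$condition)), ]
      n <- length(condition)
      latency <- exp(cell$latency_meanlog + part$u_latency +
                       rnorm(n, 0, truth$latency_sdlog))
      amp_true <- cell$amp_mean_mm + part$u_amplitude +
        rnorm(n, 0, truth$amplitude_sd_mm)
      p_ns <- plogis(cell$noshift_intercept + part$u_noshift +
                       truth$noshift_slope_per_mm * (amp_true - cell$amp_mean_mm))
      shifted <- runif(n) >= p_ns
      amp_meas <- amp_true + rnorm(n, 0, truth$amplitude_noise_sd_mm)
      exclusion <- rep("none", n)
      exclusion[shifted & latency < 100] <- "anticipatory"
      exclusion[shifted & latency > 1000] <- "improbable"
      data.frame(participant_id = plan$participant_id[i],
                 group = plan$group[i], trial_id = seq_len(n),
                 condition = condition, shifted = shifted,
                 latency_ms = ifelse(shifted, latency, NA_real_),
                 exclusion = exclusion,
                 pupil_amplitude_mm = amp_meas,
                 amp_true_mm = amp_true,
                 pupil_valid = TRUE,
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}
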