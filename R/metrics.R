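#' Extract the gaze-shift outcome of one trial
#'
#' Latency is clocked from peripheral-stimulus onset in every condition and
#' measured as the time of the first valid sample inside the target-side AOI.
#' Rules, in order of precedence:
#'
#' * if fewer than 50% of the samples in the 1000 ms display window are
#'   valid, the trial is excluded as `no_data`;
#' * the participant must be on the central stimulus at target onset: at
#'   least 50% of the valid samples in the 100 ms before onset must fall in
#'   the central AOI (no valid samples at all also fails), else
#'   `not_on_central`;
#' * if no valid sample enters either peripheral AOI, the trial is a
#'   no-shift trial (`shifted = FALSE`, no exclusion);
#' * a first entry into the non-target AOI counts as shifted
#'   (`wrong_side = TRUE`) but yields no latency;
#' * a target-AOI entry latency strictly below 100 ms is `anticipatory`,
#'   strictly above 1000 ms `improbable`; otherwise the latency is valid.
#'
#' @param samples one trial's gaze samples (`time_ms`, `x_deg`, `y_deg`,
#'   `valid`), covering at least 200 ms before peripheral onset through the
#'   peripheral offset.
#' @param schedule_row the trial's schedule row.
#' @param aois an [aoi_set()].
#' @param central_gate_ms length of the pre-onset central-fixation check
#'   window.
#' @param min_window_valid minimum valid-sample fraction in the display
#'   window.
#' @return One-row data frame: `trial_id`, `condition`, `latency_ms` (valid
#'   latencies only), `latency_raw_ms` (observed entry time regardless of
#'   exclusion), `shifted`, `wrong_side`, `exclusion`.
#' @export
extract_gaze_shift <- function(samples, schedule_row, aois = aoi_set(),
                               central_gate_ms = 100,
                               min_window_valid = 0.5) {
  onset <- schedule_row$peripheral_onset_ms
  offset <- schedule_row$peripheral_offset_ms
  t <- samples$time_ms
  if (min(t) > onset - central_gate_ms || max(t) < offset)
    stop("alignment error: samples do not cover the trial window",
         call. = FALSE)
  valid <- as.logical(samples$valid)
  res <- data.frame(trial_id = schedule_row$trial_id,
                    condition = schedule_row$condition,
                    latency_ms = NA_real_, latency_raw_ms = NA_real_,
                    shifted = NA, wrong_side = FALSE, exclusion = "none",
                    stringsAsFactors = FALSE)
  win <- t >= onset & t < offset
  if (mean(valid[win]) < min_window_valid) {
    res$exclusion <- "no_data"
    return(res)
  }
  gate <- t >= onset - central_gate_ms & t < onset & valid
  on_central <- in_aoi(samples$x_deg[gate], samples$y_deg[gate],
                       aois$central)
  if (!any(gate) || mean(on_central) < 0.5) {
    res$exclusion <- "not_on_central"
    return(res)
  }
  after <- t >= onset & valid
  in_l <- in_aoi(samples$x_deg, samples$y_deg, aois$left) & after
  in_r <- in_aoi(samples$x_deg, samples$y_deg, aois$right) & after
  first_entry <- suppressWarnings(min(c(which(in_l), which(in_r))))
  if (!is.finite(first_entry)) {
    res$shifted <- FALSE
    return(res)
  }
  res$shifted <- TRUE
  entered <- if (in_l[first_entry]) "left" else "right"
  if (entered != schedule_row$target_side) {
    res$wrong_side <- TRUE
    return(res)
  }
  lat <- t[first_entry] - onset
  res$latency_raw_ms <- lat
  if (lat < 100) res$exclusion <- "anticipatory"
  else if (lat > 1000) res$exclusion <- "improbable"
  else res$latency_ms <- lat
  res
}

#' Apply anticipatory and improbable latency exclusions
#'
#' Trials whose observed gaze-shift latency is strictly below 100 ms
#' (anticipatory) or strictly above 1000 ms (improbable) are labeled and
#' removed from both the latency and the no-shift analyses; boundary values
#' 100 and 1000 ms are kept.
#'
#' @param outcomes trial-outcome data frame with `latency_ms` and/or
#'   `latency_raw_ms`, `exclusion`, and (for the tally) `participant_id`.
#' @return A list: `outcomes` (all rows, exclusion labels updated and
#'   excluded latencies nulled), `kept` (rows with `exclusion == "none"`),
#'   `tally` (counts per participant and exclusion reason).
#' @export
apply_latency_exclusions <- function(outcomes) {
  out <- outcomes
  raw <- out$latency_raw_ms %||% out$latency_ms
  if (is.null(out$exclusion)) out$exclusion <- "none"
  ant <- !is.na(raw) & raw < 100 & out$exclusion %in% c("none", "anticipatory")
  imp <- !is.na(raw) & raw > 1000 & out$exclusion %in% c("none", "improbable")
  out$exclusion[ant] <- "anticipatory"
  out$exclusion[imp] <- "improbable"
  if (!is.null(out$latency_ms))
    out$latency_ms[out$exclusion != "none"] <- NA_real_
  pid <- out$participant_id %||% rep("all", nrow(out))
  tally <- if (nrow(out)) {
    as.data.frame(table(participant_id = pid, reason = out$exclusion),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(participant_id = character(0), reason = character(0),
               Freq = integer(0), stringsAsFactors = FALSE)
  }
  names(tally)[3] <- "n"
  list(outcomes = out, kept = out[out$exclusion == "none", , drop = FALSE],
       tally = tally)
}

measure_valid <- function(outcomes, measure) {
  switch(measure,
         latency = outcomes$exclusion == "none" &
           !is.na(outcomes$shifted) & outcomes$shifted &
           !is.na(outcomes$latency_ms),
         noshift = outcomes$exclusion == "none" & !is.na(outcomes$shifted),
         pupil = !is.na(outcomes$pupil_valid) & outcomes$pupil_valid &
           !is.na(outcomes$pupil_amplitude_mm) &
           !(outcomes$mad_outlier %||% FALSE),
         stop_config("unknown measure '", measure, "'"))
}

#' Retain participants with enough valid trials in every condition
#'
#' A participant is retained for a given outcome measure iff every one of
#' the three experimental conditions has at least `minimum` valid trials for
#' that measure (the boundary is inclusive: 4/4/4 is retained). The rule is
#' applied independently per measure.
#'
#' @param outcomes trial-outcome data frame with `participant_id`,
#'   `condition`, and the measure-specific validity columns.
#' @param minimum minimum valid trials per condition.
#' @param measure one of `"latency"`, `"noshift"`, `"pupil"`.
#' @return A list: `retained` (participant ids), `report` (per participant:
#'   valid counts per condition and the retention flag).
#' @export
min_valid_trials_filter <- function(outcomes, minimum = 4L,
                                    measure = c("latency", "noshift",
                                                "pupil")) {
  measure <- match.arg(measure)
  ok <- measure_valid(outcomes, measure)
  pids <- unique(outcomes$participant_id)
  counts <- table(factor(outcomes$participant_id[ok], levels = pids),
                  factor(outcomes$condition[ok], levels = CONDITIONS))
  report <- as.data.frame.matrix(counts)
  report <- data.frame(participant_id = rownames(report), report,
                       row.names = NULL, check.names = FALSE,
                       stringsAsFactors = FALSE)
  report$retained <- apply(counts >= minimum, 1L, all)
  report$measure <- measure
  list(retained = report$participant_id[report$retained], report = report)
}

#' Percentage of no-shift trials per participant and condition
#'
#' `100 * no-shift / (no-shift + shifted)` over non-excluded trials; cells
#' with no usable trials are missing (`NA`), not zero.
#'
#' @param outcomes trial-outcome data frame (exclusions already applied).
#' @return Data frame `participant_id`, `condition`, `n_trials`,
#'   `noshift_pct`.
#' @export
summarize_noshift <- function(outcomes) {
  ok <- outcomes$exclusion == "none" & !is.na(outcomes$shifted)
  d <- outcomes[ok, , drop = FALSE]
  grid <- expand.grid(participant_id = unique(outcomes$participant_id),
                      condition = CONDITIONS, stringsAsFactors = FALSE)
  n <- table(factor(d$participant_id, levels = unique(outcomes$participant_id)),
             factor(d$condition, levels = CONDITIONS))
  ns <- table(factor(d$participant_id[!d$shifted],
                     levels = unique(outcomes$participant_id)),
              factor(d$condition[!d$shifted], levels = CONDITIONS))
  grid$n_trials <- as.integer(n[cbind(grid$participant_id, grid$condition)])
  noshift <- as.integer(ns[cbind(grid$participant_id, grid$condition)])
  grid$noshift_pct <- ifelse(grid$n_trials > 0,
                             100 * noshift / grid$n_trials, NA_real_)
  grid[order(grid$participant_id, grid$condition), ]
}

#' Derive per-trial outcomes for a whole cohort
#'
#' Runs gaze-shift extraction and the pupil pipeline over every trial of a
#' gaze table, then applies the latency exclusion rules and the
#' per-participant MAD outlier filter on pupil amplitudes.
#'
#' @param gaze gaze table (`participant_id`, `group`, `trial_id`, `time_ms`,
#'   `x_deg`, `y_deg`, `pupil_mm`, `valid`).
#' @param schedules stacked schedules with a `participant_id` column.
#' @param aois an [aoi_set()].
#' @param pupil_cfg a [pupil_config()].
#' @return Trial-outcome data frame with behavioral and pupil fields plus
#'   exclusion and outlier flags.
#' @export
compute_trial_outcomes <- function(gaze, schedules, aois = aoi_set(),
                                   pupil_cfg = pupil_config()) {
  gz <- as.data.frame(gaze)
  by_part <- split(gz, gz$participant_id)
  out <- vector("list", 0L)
  for (pid in unique(schedules$participant_id)) {
    sch <- schedules[schedules$participant_id == pid, , drop = FALSE]
    gp <- by_part[[pid]]
    grp <- gp$group[1]
    by_trial <- split(gp, gp$trial_id)
    rows <- lapply(seq_len(nrow(sch)), function(k) {
      s_row <- sch[k, ]
      tr <- by_trial[[as.character(s_row$trial_id)]]
      beh <- extract_gaze_shift(tr, s_row, aois)
      pup <- tryCatch(process_pupil(tr[c("time_ms", "pupil_mm", "valid")],
                                    s_row, pupil_cfg),
                      error = function(e)
                        data.frame(pupil_baseline_mm = NA_real_,
                                   pupil_amplitude_mm = NA_real_,
                                   valid_fraction = 0, pupil_valid = FALSE))
      cbind(data.frame(participant_id = pid, group = grp,
                       stringsAsFactors = FALSE), beh, pup)
    })
    out[[length(out) + 1L]] <- data.table::rbindlist(rows)
  }
  outcomes <- as.data.frame(data.table::rbindlist(out))
  outcomes <- apply_latency_exclusions(outcomes)$outcomes
  mad <- mad_outlier_filter(outcomes[c("participant_id", "group",
                                       "pupil_amplitude_mm")], pupil_cfg)
  outcomes$mad_outlier <- mad$data$mad_outlier
  outcomes$pupil_valid <- outcomes$pupil_valid & !outcomes$mad_outlier
  outcomes
}
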