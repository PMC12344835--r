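#' Pupil preprocessing configuration
#'
#' Constants of the pupil pipeline: linear interpolation over invalid runs
#' strictly shorter than 100 ms, an 80 ms moving-median filter, baseline as
#' the median over the 1000-666 ms interval before peripheral-stimulus
#' onset, phasic amplitude as the baseline-subtracted median over the
#' 0-1500 ms response window, a 30% minimum valid-sample fraction, and a
#' per-participant 3 x MAD outlier rule (consistency constant 1.4826). All
#' windows are closed on the left and open on the right, in trial-local
#' milliseconds.
#'
#' @param max_interp_gap_ms invalid runs strictly shorter than this are
#'   linearly interpolated.
#' @param median_window_ms width of the centered moving-median window.
#' @param baseline_window_ms interval relative to peripheral onset.
#' @param response_window_ms interval relative to peripheral onset.
#' @param min_valid_fraction minimum fraction of valid samples over the
#'   union of the two windows for a usable amplitude.
#' @param mad_k,mad_scale MAD multiplier and consistency constant.
#' @return A list of class `pupil_config`.
#' @export
pupil_config <- function(max_interp_gap_ms = 100, median_window_ms = 80,
                         baseline_window_ms = c(-1000, -666),
                         response_window_ms = c(0, 1500),
                         min_valid_fraction = 0.30, mad_k = 3,
                         mad_scale = 1.4826) {
  if (baseline_window_ms[1] >= baseline_window_ms[2] ||
      response_window_ms[1] >= response_window_ms[2])
    stop_config("windows must be non-degenerate intervals")
  if (baseline_window_ms[2] > response_window_ms[1])
    stop_config("baseline window must precede the response window")
  if (min_valid_fraction <= 0 || min_valid_fraction > 1)
    stop_config("min_valid_fraction must lie in (0, 1]")
  structure(list(max_interp_gap_ms = max_interp_gap_ms,
                 median_window_ms = median_window_ms,
                 baseline_window_ms = baseline_window_ms,
                 response_window_ms = response_window_ms,
                 min_valid_fraction = min_valid_fraction,
                 mad_k = mad_k, mad_scale = mad_scale),
            class = "pupil_config")
}

pupil_stage <- function(trace) attr(trace, "pupil_stage") %||% "raw"

require_stage <- function(trace, wanted, caller) {
  have <- pupil_stage(trace)
  stages <- c("raw", "interpolated", "filtered")
  if (match(have, stages) < match(wanted, stages))
    stop(caller, ": trace is at stage '", have, "'; the pipeline order is ",
         "interpolate_gaps() -> pupil_median_filter() -> compute_amplitude()",
         call. = FALSE)
  invisible(TRUE)
}

#' Linearly interpolate short invalid pupil runs
#'
#' Invalid runs strictly shorter than `max_interp_gap_ms` (run duration =
#' number of missing samples times the nominal sample interval) that are
#' bounded by valid samples on both sides are filled by linear interpolation
#' between the bounding pupil values and flagged in an `interpolated`
#' column; longer runs, and runs touching either end of the trace, remain
#' invalid. Idempotent.
#'
#' @param trace data frame with `time_ms`, `pupil_mm`, `valid`.
#' @param config a [pupil_config()].
#' @return The trace with gaps filled, an `interpolated` column, and its
#'   pipeline stage advanced to `"interpolated"`.
#' @export
interpolate_gaps <- function(trace, config = pupil_config()) {
  if (!all(c("time_ms", "pupil_mm", "valid") %in% names(trace)))
    stop("schema error: trace needs time_ms, pupil_mm, valid", call. = FALSE)
  trace$valid <- as.logical(trace$valid)
  if (is.null(trace$interpolated)) trace$interpolated <- FALSE
  dt <- nominal_dt(trace$time_ms)
  runs <- run_table(!trace$valid)
  n <- nrow(trace)
  for (k in seq_len(nrow(runs))) {
    if (!isTRUE(runs$value[k])) next
    len_ms <- (runs$end[k] - runs$start[k] + 1L) * dt
    if (len_ms >= config$max_interp_gap_ms) next
    lo <- runs$start[k] - 1L
    hi <- runs$end[k] + 1L
    if (lo < 1L || hi > n) next                      # touches a trace end
    idx <- runs$start[k]:runs$end[k]
    w <- (trace$time_ms[idx] - trace$time_ms[lo]) /
      (trace$time_ms[hi] - trace$time_ms[lo])
    trace$pupil_mm[idx] <- trace$pupil_mm[lo] +
      w * (trace$pupil_mm[hi] - trace$pupil_mm[lo])
    trace$valid[idx] <- TRUE
    trace$interpolated[idx] <- TRUE
  }
  attr(trace, "pupil_stage") <- "interpolated"
  trace
}

#' Moving-median filter for pupil traces
#'
#' Each valid sample is replaced by the median of the valid samples within a
#' centered `median_window_ms` window (inclusive of both half-window edges);
#' invalid samples propagate as invalid. At trace ends the window is
#' truncated. A fast `runmed()` path is used for fully valid, regularly
#' sampled traces; otherwise each window is evaluated directly.
#'
#' @inheritParams interpolate_gaps
#' @return The filtered trace, stage `"filtered"`.
#' @export
pupil_median_filter <- function(trace, config = pupil_config()) {
  require_stage(trace, "interpolated", "pupil_median_filter")
  t <- trace$time_ms
  x <- trace$pupil_mm
  v <- trace$valid
  n <- length(t)
  half <- config$median_window_ms / 2
  dt <- nominal_dt(t)
  regular <- n >= 3L && max(abs(diff(t) - dt)) < 1e-6
  out <- x
  if (all(v) && regular) {
    k <- 2L * floor(half / dt + 1e-9) + 1L
    if (k >= 3L && k <= n) {
      out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
      hw <- (k - 1L) %/% 2L
      for (i in c(seq_len(min(hw, n)), seq.int(max(1L, n - hw + 1L), n)))
        out[i] <- stats::median(x[abs(t - t[i]) <= half + 1e-9])
    } else if (k > n) {
      for (i in seq_len(n))
        out[i] <- stats::median(x[abs(t - t[i]) <= half + 1e-9])
    }
  } else {
    eps <- 1e-9
    j_lo <- findInterval(t - half - eps, t) + 1L
    j_hi <- findInterval(t + half + eps, t)
    for (i in which(v)) {
      idx <- j_lo[i]:j_hi[i]
      idx <- idx[v[idx]]
      out[i] <- stats::median(x[idx])
    }
    out[!v] <- NA_real_
  }
  trace$pupil_mm <- out
  attr(trace, "pupil_stage") <- "filtered"
  trace
}

#' Baseline and phasic dilation amplitude of one trial
#'
#' Baseline is the median filtered pupil size over the baseline window
#' before peripheral onset; the amplitude is the median over the response
#' window after onset minus the baseline. The valid fraction is computed
#' over the union of both windows, counting interpolated samples as valid;
#' the amplitude is marked unusable when it falls below
#' `min_valid_fraction`.
#'
#' @param trace a filtered trace from [pupil_median_filter()].
#' @param schedule_row one row of a `trial_schedule` (supplies
#'   `peripheral_onset_ms`).
#' @param config a [pupil_config()].
#' @return One-row data frame: `pupil_baseline_mm`, `pupil_amplitude_mm`,
#'   `valid_fraction`, `pupil_valid`.
#' @export
compute_amplitude <- function(trace, schedule_row, config = pupil_config()) {
  require_stage(trace, "filtered", "compute_amplitude")
  onset <- schedule_row$peripheral_onset_ms
  t <- trace$time_ms
  b_in <- t >= onset + config$baseline_window_ms[1] &
    t < onset + config$baseline_window_ms[2]
  r_in <- t >= onset + config$response_window_ms[1] &
    t < onset + config$response_window_ms[2]
  if (!any(b_in))
    stop("window error: baseline window lies outside the trace", call. = FALSE)
  if (!any(r_in))
    stop("window error: response window lies outside the trace", call. = FALSE)
  u_in <- b_in | r_in
  valid_fraction <- mean(trace$valid[u_in])
  baseline <- stats::median(trace$pupil_mm[b_in & trace$valid])
  response <- stats::median(trace$pupil_mm[r_in & trace$valid])
  amplitude <- response - baseline
  ok <- valid_fraction >= config$min_valid_fraction &&
    is.finite(amplitude)
  data.frame(pupil_baseline_mm = if (ok) baseline else NA_real_,
             pupil_amplitude_mm = if (ok) amplitude else NA_real_,
             valid_fraction = valid_fraction,
             pupil_valid = ok)
}

#' Per-participant MAD outlier removal of pupil amplitudes
#'
#' Flags, separately per participant, amplitudes farther than
#' `mad_k * mad_scale * median(|x - median(x)|)` from the participant's
#' median. Participants with fewer than 4 amplitudes are skipped with a
#' warning; a participant whose MAD is exactly 0 has nothing removed and
#' triggers a degeneracy warning.
#'
#' @param amplitudes data frame with `participant_id`, `pupil_amplitude_mm`,
#'   and optionally `group`.
#' @param config a [pupil_config()].
#' @return A list: `data` (input plus logical `mad_outlier`), `kept` (rows
#'   surviving the filter), `removal` (per-group, or overall, removal
#'   fractions).
#' @export
mad_outlier_filter <- function(amplitudes, config = pupil_config()) {
  stopifnot(all(c("participant_id", "pupil_amplitude_mm") %in%
                  names(amplitudes)))
  amplitudes$mad_outlier <- FALSE
  for (pid in unique(amplitudes$participant_id)) {
    idx <- which(amplitudes$participant_id == pid &
                   !is.na(amplitudes$pupil_amplitude_mm))
    x <- amplitudes$pupil_amplitude_mm[idx]
    if (length(x) < 4L) {
      warning("participant ", pid, ": fewer than 4 amplitudes; MAD filter ",
              "skipped", call. = FALSE)
      next
    }
    med <- stats::median(x)
    mad_raw <- stats::median(abs(x - med))
    if (mad_raw == 0) {
      warning("participant ", pid, ": MAD is 0 (degenerate spread); ",
              "nothing removed", call. = FALSE)
      next
    }
    thr <- config$mad_k * config$mad_scale * mad_raw
    amplitudes$mad_outlier[idx] <- abs(x - med) > thr
  }
  grp <- if ("group" %in% names(amplitudes)) amplitudes$group else
    rep("all", nrow(amplitudes))
  removal <- aggregate(list(removed_fraction = amplitudes$mad_outlier),
                       by = list(group = grp), FUN = mean)
  list(data = amplitudes,
       kept = amplitudes[!amplitudes$mad_outlier, , drop = FALSE],
       removal = removal)
}

#' Run the full per-trial pupil pipeline
#'
#' Convenience wrapper enforcing the stage order interpolate -> median
#' filter -> amplitude on one trial's trace.
#'
#' @inheritParams compute_amplitude
#' @return As [compute_amplitude()].
#' @export
process_pupil <- function(trace, schedule_row, config = pupil_config()) {
  trace <- interpolate_gaps(trace, config)
  trace <- pupil_median_filter(trace, config)
  compute_amplitude(trace, schedule_row, config)
}
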