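#' I-VT velocity-threshold filter configuration
#'
#' Defaults follow standard I-VT practice for this paradigm: a 30 deg/s
#' velocity threshold with a 20 ms velocity window. Fixations shorter than
#' `min_fixation_ms` that are flanked by saccades on both sides are absorbed
#' into the surrounding saccade; set it to 0 to disable merging.
#'
#' @param velocity_threshold_deg_s angular-speed threshold; samples with
#'   speed strictly greater are saccade samples (a run at exactly the
#'   threshold is a fixation).
#' @param window_ms width of the centered velocity window; must cover at
#'   least two sample intervals at the trace's rate.
#' @param min_fixation_ms minimum fixation duration before merging.
#' @return A list of class `ivt_config`.
#' @export
ivt_config <- function(velocity_threshold_deg_s = 30, window_ms = 20,
                       min_fixation_ms = 60) {
  if (velocity_threshold_deg_s <= 0) stop_config("threshold must be > 0")
  if (window_ms <= 0) stop_config("window_ms must be > 0")
  structure(list(velocity_threshold_deg_s = velocity_threshold_deg_s,
                 window_ms = window_ms, min_fixation_ms = min_fixation_ms),
            class = "ivt_config")
}

#' Per-sample angular speed for the I-VT filter
#'
#' The speed at sample i is the Euclidean (small-angle) distance between the
#' valid samples nearest the two edges of a `window_ms` window centered on
#' sample i, divided by their time separation. At trace ends the window is
#' truncated, never extrapolated. The speed is `NA` where the sample itself
#' is invalid or where the window does not contain two distinct valid
#' samples (e.g. around blink runs).
#'
#' @param samples data frame with `time_ms`, `x_deg`, `y_deg`, `valid`.
#' @param config an [ivt_config()].
#' @return Numeric vector of speeds (deg/s), aligned to `samples`.
#' @export
compute_velocity <- function(samples, config = ivt_config()) {
  t <- samples$time_ms
  v <- as.logical(samples$valid)
  n <- length(t)
  if (sum(v) < 2L)
    stop("empty-velocity error: fewer than two valid samples", call. = FALSE)
  half <- config$window_ms / 2
  dtn <- nominal_dt(t)
  if (config$window_ms < 2 * dtn - 1e-9)
    stop_config("window_ms must cover at least two sample intervals")
  eps <- 1e-9
  j_lo <- findInterval(t - half - eps, t) + 1L
  j_hi <- findInterval(t + half + eps, t)
  iv <- which(v)
  # first valid index >= j_lo, last valid index <= j_hi
  a_pos <- findInterval(j_lo - 0.5, iv) + 1L
  b_pos <- findInterval(j_hi + 0.5, iv)
  a <- rep(NA_integer_, n)
  in_a <- a_pos <= length(iv)                  # a_pos is always >= 1
  a[in_a] <- iv[a_pos[in_a]]
  b <- rep(NA_integer_, n)
  in_b <- b_pos >= 1L
  b[in_b] <- iv[b_pos[in_b]]
  ok <- v & !is.na(a) & !is.na(b) & a < b
  speed <- rep(NA_real_, n)
  ai <- a[ok]; bi <- b[ok]
  dist <- sqrt((samples$x_deg[bi] - samples$x_deg[ai])^2 +
                 (samples$y_deg[bi] - samples$y_deg[ai])^2)
  speed[ok] <- dist / ((t[bi] - t[ai]) / 1000)
  speed
}

#' Classify samples into fixation, saccade, and gap events
#'
#' Contiguous runs of valid samples with speed strictly above the threshold
#' become saccades; runs at or below the threshold become fixations; invalid
#' runs become gap events. Valid samples whose velocity is undefined are
#' treated as fixation samples (no evidence of movement). Fixations shorter
#' than `min_fixation_ms` lying strictly between two saccades are absorbed
#' into a single saccade. Events tile the trace: each sample owns one
#' nominal sample interval, so event durations sum to
#' `n_samples * dt`.
#'
#' @param samples data frame with `time_ms`, `x_deg`, `y_deg`, `valid`.
#' @param velocities per-sample speeds from [compute_velocity()], or `NULL`
#'   to compute them.
#' @param config an [ivt_config()].
#' @return A `data.frame` of class `gaze_events` with `kind`, `start_ms`,
#'   `end_ms`, `duration_ms`, `centroid_x_deg`, `centroid_y_deg` (fixations
#'   only), `peak_velocity_deg_s`; attribute `dt_ms` holds the nominal
#'   sample interval.
#' @export
classify_ivt <- function(samples, velocities = NULL, config = ivt_config()) {
  if (is.null(velocities)) velocities <- compute_velocity(samples, config)
  t <- samples$time_ms
  valid <- as.logical(samples$valid)
  dt <- nominal_dt(t)
  kind <- ifelse(!valid, "gap",
                 ifelse(!is.na(velocities) &
                          velocities > config$velocity_threshold_deg_s,
                        "saccade", "fixation"))
  runs <- run_table(kind)
  # absorb short fixations strictly between two saccades
  if (config$min_fixation_ms > 0 && nrow(runs) >= 3L) {
    dur <- (runs$end - runs$start + 1L) * dt
    for (k in 2:(nrow(runs) - 1L)) {
      if (runs$value[k] == "fixation" && dur[k] < config$min_fixation_ms &&
          runs$value[k - 1L] == "saccade" && runs$value[k + 1L] == "saccade")
        runs$value[k] <- "saccade"
    }
    kind <- rep(runs$value, runs$end - runs$start + 1L)
    runs <- run_table(kind)
  }
  ev <- data.frame(kind = runs$value,
                   start_ms = t[runs$start],
                   end_ms = t[runs$end] + dt,
                   stringsAsFactors = FALSE)
  ev$duration_ms <- ev$end_ms - ev$start_ms
  ev$centroid_x_deg <- NA_real_
  ev$centroid_y_deg <- NA_real_
  ev$peak_velocity_deg_s <- NA_real_
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start[k]:runs$end[k]
    if (ev$kind[k] == "fixation") {
      ev$centroid_x_deg[k] <- mean(samples$x_deg[idx], na.rm = TRUE)
      ev$centroid_y_deg[k] <- mean(samples$y_deg[idx], na.rm = TRUE)
    }
    if (ev$kind[k] != "gap" && any(!is.na(velocities[idx])))
      ev$peak_velocity_deg_s[k] <- max(velocities[idx], na.rm = TRUE)
  }
  attr(ev, "dt_ms") <- dt
  class(ev) <- c("gaze_events", "data.frame")
  ev
}
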