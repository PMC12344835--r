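# Shared fixtures and independent brute-force reference implementations.
# The references are deliberately naive (per-sample loops) so they share no
# code path with the package.

noiseless_truth <- function(...) {
  simulation_truth(dropout_rate = 0, gaze_noise_sd_deg = 0,
                   pupil_noise_sd_mm = 0, drift_sd_mm = 0,
                   amplitude_noise_sd_mm = 0, ...)
}

# simple random gaze trace: random-walk position, optional invalid runs
random_trace <- function(n = 120, rate = 120, p_invalid_run = 0.05,
                         pos_sd = 0.5) {
  dt <- 1000 / rate
  t <- seq(0, by = dt, length.out = n)
  x <- cumsum(rnorm(n, 0, pos_sd))
  y <- cumsum(rnorm(n, 0, pos_sd))
  valid <- rep(TRUE, n)
  k <- rpois(1, p_invalid_run * n / 5)
  if (k > 0) {
    starts <- sample.int(n, k)
    for (s in starts) valid[s:min(n, s + sample(2:8, 1))] <- FALSE
  }
  data.frame(time_ms = t, x_deg = x, y_deg = y,
             pupil_mm = 3 + cumsum(rnorm(n, 0, 0.01)), valid = valid)
}

velocity_oracle <- function(samples, cfg = ivt_config()) {
  t <- samples$time_ms
  v <- as.logical(samples$valid)
  n <- length(t)
  half <- cfg$window_ms / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!v[i]) next
    idx <- which(t >= t[i] - half - 1e-9 & t <= t[i] + half + 1e-9 & v)
    if (length(idx) < 2L) next
    a <- min(idx); b <- max(idx)
    if (a == b) next
    d <- sqrt((samples$x_deg[b] - samples$x_deg[a])^2 +
                (samples$y_deg[b] - samples$y_deg[a])^2)
    out[i] <- d / ((t[b] - t[a]) / 1000)
  }
  out
}

events_oracle <- function(samples, cfg = ivt_config()) {
  t <- samples$time_ms
  vel <- velocity_oracle(samples, cfg)
  dt <- median(diff(t))
  cls <- ifelse(!samples$valid, "gap",
                ifelse(!is.na(vel) & vel > cfg$velocity_threshold_deg_s,
                       "saccade", "fixation"))
  # build maximal runs by walking the trace
  runs <- list()
  s <- 1L
  for (i in seq_along(cls)[-1]) {
    if (cls[i] != cls[s]) {
      runs[[length(runs) + 1L]] <- c(s, i - 1L)
      s <- i
    }
  }
  runs[[length(runs) + 1L]] <- c(s, length(cls))
  lab <- vapply(runs, function(r) cls[r[1]], "")
  if (cfg$min_fixation_ms > 0 && length(runs) >= 3L) {
    for (k in 2:(length(runs) - 1L)) {
      dur <- (runs[[k]][2] - runs[[k]][1] + 1L) * dt
      if (lab[k] == "fixation" && dur < cfg$min_fixation_ms &&
          lab[k - 1L] == "saccade" && lab[k + 1L] == "saccade")
        lab[k] <- "saccade"
    }
  }
  # merge adjacent runs with equal labels
  out <- data.frame(kind = character(0), start_ms = numeric(0),
                    end_ms = numeric(0))
  for (k in seq_along(runs)) {
    if (nrow(out) > 0 && out$kind[nrow(out)] == lab[k]) {
      out$end_ms[nrow(out)] <- t[runs[[k]][2]] + dt
    } else {
      out <- rbind(out, data.frame(kind = lab[k],
                                   start_ms = t[runs[[k]][1]],
                                   end_ms = t[runs[[k]][2]] + dt))
    }
  }
  out
}

median_filter_oracle <- function(trace, cfg = pupil_config()) {
  t <- trace$time_ms
  x <- trace$pupil_mm
  v <- as.logical(trace$valid)
  half <- cfg$median_window_ms / 2
  out <- rep(NA_real_, length(t))
  for (i in seq_along(t)) {
    if (!v[i]) next
    idx <- which(abs(t - t[i]) <= half + 1e-9 & v)
    out[i] <- median(x[idx])
  }
  out
}

interpolate_oracle <- function(trace, cfg = pupil_config()) {
  t <- trace$time_ms
  x <- trace$pupil_mm
  v <- as.logical(trace$valid)
  dt <- median(diff(t))
  n <- length(t)
  i <- 1L
  while (i <= n) {
    if (!v[i]) {
      j <- i
      while (j < n && !v[j + 1L]) j <- j + 1L
      if ((j - i + 1L) * dt < cfg$max_interp_gap_ms && i > 1L && j < n) {
        for (k in i:j)
          x[k] <- x[i - 1L] + (t[k] - t[i - 1L]) / (t[j + 1L] - t[i - 1L]) *
            (x[j + 1L] - x[i - 1L])
        v[i:j] <- TRUE
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  list(pupil_mm = x, valid = v)
}

mad_keep_oracle <- function(x, k = 3, scale = 1.4826) {
  med <- median(x)
  madr <- median(abs(x - med))
  if (madr == 0) return(rep(TRUE, length(x)))
  abs(x - med) <= k * scale * madr
}

# expected measured amplitude for a simulated trial: the response-window
# median of the sampled kernel minus the baseline-window median, scaled by
# the true peak amplitude (numeric evaluation at the trial's sample times)
kernel_amplitude_oracle <- function(per_on, cue_on, amp, rate,
                                    truth = simulation_truth()) {
  dt <- 1000 / rate
  t0 <- min(0, per_on - 1000 - dt)
  times <- seq(t0, per_on + 1100, by = dt)
  lock <- if (!is.na(cue_on)) cue_on else per_on
  k <- pupil_kernel(times - lock, truth$kernel_latency_ms, truth$kernel_shape)
  rw <- times >= per_on & times < per_on + 1500
  bw <- times >= per_on - 1000 & times < per_on - 666
  amp * (median(k[rw]) - median(k[bw]))
}

# constructed single-trial gaze stream: fixate center, step into an AOI at a
# chosen entry time (1000 Hz so boundaries are exact)
synthetic_shift_trial <- function(entry_ms = 250, onset = 1200, side = "right",
                                  enter = TRUE, rate = 1000,
                                  end_pad = 100) {
  dt <- 1000 / rate
  t <- seq(0, onset + 1000 + end_pad, by = dt)
  x <- rep(0, length(t))
  if (enter) x[t >= onset + entry_ms] <- if (side == "right") 10 else -10
  schedule <- data.frame(trial_id = 1L, condition = "overlap_silent",
                         central_onset_ms = 0L,
                         central_offset_ms = onset + 1000L,
                         peripheral_onset_ms = onset,
                         peripheral_offset_ms = onset + 1000L,
                         target_side = "right", cue_onset_ms = NA_integer_,
                         session_start_ms = 0L)
  list(samples = data.frame(time_ms = t, x_deg = x, y_deg = 0,
                            pupil_mm = 3, valid = TRUE),
       schedule = schedule)
}
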