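#' Task design configuration for a gap-overlap session
#'
#' Encodes the trial counts and timing constants of the gap-overlap paradigm:
#' a central stimulus shown for 800-1700 ms, followed by a 1000 ms peripheral
#' target that either follows a 120-200 ms blank gap (gap condition) or
#' appears while the central stimulus stays on (overlap conditions). On
#' overlap-cued trials an auditory alerting cue precedes the target by
#' 0-500 ms. The default counts (21/18/19, 58 trials in total) reproduce the
#' published session design.
#'
#' @param n_gap,n_overlap_silent,n_overlap_cued trials per condition.
#' @param central_duration_range_ms closed interval (ms) from which the
#'   central-stimulus display duration is drawn uniformly.
#' @param gap_duration_range_ms closed interval (ms) for the blank gap on gap
#'   trials.
#' @param peripheral_duration_ms display duration (ms) of the peripheral
#'   target.
#' @param cue_lead_range_ms closed interval (ms) for how far the auditory cue
#'   precedes the target on overlap-cued trials.
#' @param inter_trial_interval_ms pause (ms) between trials, used only to
#'   accumulate session-level start times.
#' @param max_side_run longest permitted run of identical target sides.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_gap = 21L, n_overlap_silent = 18L,
                        n_overlap_cued = 19L,
                        central_duration_range_ms = c(800L, 1700L),
                        gap_duration_range_ms = c(120L, 200L),
                        peripheral_duration_ms = 1000L,
                        cue_lead_range_ms = c(0L, 500L),
                        inter_trial_interval_ms = 500L,
                        max_side_run = 3L) {
  cfg <- list(n_gap = as.integer(n_gap),
              n_overlap_silent = as.integer(n_overlap_silent),
              n_overlap_cued = as.integer(n_overlap_cued),
              central_duration_range_ms = as.integer(central_duration_range_ms),
              gap_duration_range_ms = as.integer(gap_duration_range_ms),
              peripheral_duration_ms = as.integer(peripheral_duration_ms),
              cue_lead_range_ms = as.integer(cue_lead_range_ms),
              inter_trial_interval_ms = as.integer(inter_trial_interval_ms),
              max_side_run = as.integer(max_side_run))
  for (nm in c("central_duration_range_ms", "gap_duration_range_ms",
               "cue_lead_range_ms")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || anyNA(r)) stop_config(nm, " must be a length-2 interval")
    if (r[1] > r[2]) stop_config(nm, ": interval minimum exceeds maximum")
  }
  if (any(c(cfg$n_gap, cfg$n_overlap_silent, cfg$n_overlap_cued) < 0L))
    stop_config("trial counts must be non-negative")
  if (cfg$peripheral_duration_ms <= 0L || cfg$inter_trial_interval_ms < 0L)
    stop_config("durations must be positive")
  if (cfg$central_duration_range_ms[1] <= 0L || cfg$gap_duration_range_ms[1] <= 0L ||
      cfg$cue_lead_range_ms[1] < 0L)
    stop_config("durations must be positive")
  class(cfg) <- "task_config"
  cfg
}

#' Rectangular area of interest
#'
#' @param x,y center in degrees of visual angle ((0, 0) = screen center).
#' @param width,height extent in degrees; membership is closed on all edges.
#' @return Named numeric vector `c(x, y, width, height)`.
#' @export
aoi_rect <- function(x, y, width, height) {
  if (width <= 0 || height <= 0) stop_config("AOI width/height must be positive")
  c(x = x, y = y, width = width, height = height)
}

#' Areas of interest for the gap-overlap display
#'
#' Default geometry: a 4 x 4 degree central AOI at fixation and 6 x 6 degree
#' peripheral AOIs centered 10 degrees left and right of fixation.
#'
#' @param central,left,right rectangles from [aoi_rect()].
#' @return A list of class `aoi_set`.
#' @export
aoi_set <- function(central = aoi_rect(0, 0, 4, 4),
                    left = aoi_rect(-10, 0, 6, 6),
                    right = aoi_rect(10, 0, 6, 6)) {
  aois <- list(central = central, left = left, right = right)
  cmb <- utils::combn(names(aois), 2)
  for (k in seq_len(ncol(cmb))) {
    a <- aois[[cmb[1, k]]]; b <- aois[[cmb[2, k]]]
    if (abs(a["x"] - b["x"]) < (a["width"] + b["width"]) / 2 &&
        abs(a["y"] - b["y"]) < (a["height"] + b["height"]) / 2)
      stop_config("AOIs '", cmb[1, k], "' and '", cmb[2, k], "' overlap")
  }
  class(aois) <- "aoi_set"
  aois
}

#' Test points for AOI membership
#'
#' @param x_deg,y_deg gaze coordinates (degrees).
#' @param rect rectangle from [aoi_rect()].
#' @return Logical vector; `NA` coordinates give `FALSE`.
#' @export
in_aoi <- function(x_deg, y_deg, rect) {
  inside <- abs(x_deg - rect[["x"]]) <= rect[["width"]] / 2 &
    abs(y_deg - rect[["y"]]) <= rect[["height"]] / 2
  inside & !is.na(inside)
}

# Target-side sequence balanced within rounding, with no run longer than
# max_run. Constructed left-to-right, drawing each side with probability
# proportional to its remaining count and excluding a side that would extend
# a run beyond max_run; if the balance constraint corners the construction
# into a long run, the whole sequence is redrawn (still deterministic under
# the caller's seed).
balanced_sides <- function(n, max_run = 3L) {
  if (n == 0L) return(character(0))
  for (attempt in 1:1000) {
    remaining <- c(left = ceiling(n / 2), right = floor(n / 2))
    out <- character(n)
    run <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      allowed <- names(remaining)[remaining > 0L]
      if (i > 1L && run >= max_run) allowed <- setdiff(allowed, out[i - 1L])
      if (length(allowed) == 0L) {
        ok <- FALSE
        break
      }
      pick <- if (length(allowed) == 1L) allowed else
        sample(allowed, 1L, prob = remaining[allowed])
      out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
      run <- if (i > 1L && out[i] == out[i - 1L]) run + 1L else 1L
    }
    if (ok) return(out)
  }
  stop("could not construct a side sequence satisfying the run constraint")
}

#' Generate a randomized session schedule
#'
#' Draws one trial schedule per configured trial: a uniformly random
#' permutation of the condition multiset, uniform integer timing draws over
#' the configured intervals, and a pseudo-random balanced target-side
#' sequence. Times are trial-local integer milliseconds with the central
#' onset at 0; `session_start_ms` accumulates absolute session time using the
#' inter-trial interval.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the schedule is a pure function of
#'   `(config, seed)`.
#' @return A `data.frame` of class `trial_schedule` with one row per trial:
#'   `trial_id`, `condition`, `central_onset_ms`, `central_offset_ms`,
#'   `peripheral_onset_ms`, `peripheral_offset_ms`, `target_side`,
#'   `cue_onset_ms` (`NA` except on overlap-cued trials), `session_start_ms`.
#' @export
generate_schedule <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  counts <- c(gap = config$n_gap, overlap_silent = config$n_overlap_silent,
              overlap_cued = config$n_overlap_cued)
  n <- sum(counts)
  with_seed(seed, {
    condition <- sample(rep(names(counts), counts))
    side <- balanced_sides(n, config$max_side_run)
    central_dur <- sample(seq(config$central_duration_range_ms[1],
                              config$central_duration_range_ms[2]), n,
                          replace = TRUE)
    gap_dur <- sample(seq(config$gap_duration_range_ms[1],
                          config$gap_duration_range_ms[2]), n, replace = TRUE)
    cue_lead <- sample(seq(config$cue_lead_range_ms[1],
                           config$cue_lead_range_ms[2]), n, replace = TRUE)
    per_dur <- config$peripheral_duration_ms
    is_gap <- condition == "gap"
    peripheral_onset <- ifelse(is_gap, central_dur + gap_dur, central_dur)
    peripheral_offset <- peripheral_onset + per_dur
    central_offset <- ifelse(is_gap, central_dur, peripheral_offset)
    cue_onset <- ifelse(condition == "overlap_cued",
                        peripheral_onset - cue_lead, NA_integer_)
    trial_end <- peripheral_offset
    session_start <- cumsum(c(0L, head(trial_end, -1L) +
                                config$inter_trial_interval_ms))[seq_len(n)]
    sched <- data.frame(
      trial_id = seq_len(n),
      condition = condition,
      central_onset_ms = rep(0L, n),
      central_offset_ms = as.integer(central_offset),
      peripheral_onset_ms = as.integer(peripheral_onset),
      peripheral_offset_ms = as.integer(peripheral_offset),
      target_side = side,
      cue_onset_ms = as.integer(cue_onset),
      session_start_ms = as.integer(session_start),
      stringsAsFactors = FALSE)
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

#' Validate a trial schedule against the task-design invariants
#'
#' Checks, per trial: condition is known; the gap duration lies in the
#' configured 120-200 ms interval (gap trials); the central stimulus stays on
#' through the target (overlap trials); the peripheral display lasts the
#' configured 1000 ms; the central display duration (central onset to
#' peripheral onset for overlap, to central offset for gap) lies in
#' 800-1700 ms; a cue onset is present iff the condition is overlap-cued,
#' with a lead in 0-500 ms.
#'
#' @param schedule a `trial_schedule` data frame.
#' @param config the [task_config()] supplying the intervals.
#' @return A `data.frame` with columns `trial_id`, `rule`, `detail`; zero
#'   rows iff the schedule is valid.
#' @export
validate_schedule <- function(schedule, config = task_config()) {
  v <- list()
  bad <- function(ids, rule, detail) {
    if (length(ids)) v[[length(v) + 1L]] <<-
        data.frame(trial_id = ids, rule = rule, detail = detail,
                   stringsAsFactors = FALSE)
  }
  s <- schedule
  bad(s$trial_id[!s$condition %in% CONDITIONS], "condition",
      "unknown condition label")
  gr <- config$gap_duration_range_ms
  g <- s$condition == "gap"
  gapdur <- s$peripheral_onset_ms - s$central_offset_ms
  bad(s$trial_id[g & (gapdur < gr[1] | gapdur > gr[2])], "gap_duration",
      sprintf("gap duration outside [%d, %d] ms", gr[1], gr[2]))
  ov <- s$condition %in% c("overlap_silent", "overlap_cued")
  bad(s$trial_id[ov & s$central_offset_ms < s$peripheral_offset_ms],
      "overlap_central_on", "central stimulus ends before peripheral offset")
  perdur <- s$peripheral_offset_ms - s$peripheral_onset_ms
  bad(s$trial_id[perdur != config$peripheral_duration_ms],
      "peripheral_duration",
      sprintf("peripheral display != %d ms", config$peripheral_duration_ms))
  cr <- config$central_duration_range_ms
  cdur <- ifelse(g, s$central_offset_ms, s$peripheral_onset_ms) -
    s$central_onset_ms
  bad(s$trial_id[cdur < cr[1] | cdur > cr[2]], "central_duration",
      sprintf("central display outside [%d, %d] ms", cr[1], cr[2]))
  cued <- s$condition == "overlap_cued"
  bad(s$trial_id[cued & is.na(s$cue_onset_ms)], "cue_presence",
      "overlap-cued trial without cue onset")
  bad(s$trial_id[!cued & !is.na(s$cue_onset_ms)], "cue_presence",
      "cue onset on a non-cued trial")
  lr <- config$cue_lead_range_ms
  lead <- s$peripheral_onset_ms - s$cue_onset_ms
  bad(s$trial_id[cued & !is.na(s$cue_onset_ms) &
                   (lead < lr[1] | lead > lr[2])], "cue_lead",
      sprintf("cue lead outside [%d, %d] ms", lr[1], lr[2]))
  bad(s$trial_id[!s$target_side %in% c("left", "right")], "target_side",
      "target side must be left or right")
  if (length(v)) do.call(rbind, v)[order(do.call(rbind, v)$trial_id), ] else
    data.frame(trial_id = integer(0), rule = character(0),
               detail = character(0), stringsAsFactors = FALSE)
}

#' Read/write schedules as JSON
#'
#' Schedules serialize as a JSON array of per-trial records with integer
#' millisecond fields; `cue_onset_ms` is `null` on non-cued trials. The
#' round trip is lossless.
#'
#' @param schedule a `trial_schedule`.
#' @param path file path.
#' @return `read_schedule_json` returns a `trial_schedule` data frame.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(as.data.frame(schedule), path, dataframe = "rows",
                       na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  s <- jsonlite::fromJSON(path)
  need <- c("trial_id", "condition", "central_onset_ms", "central_offset_ms",
            "peripheral_onset_ms", "peripheral_offset_ms", "target_side",
            "session_start_ms")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("schema error: missing column '", miss[1], "'",
                         call. = FALSE)
  if (is.null(s$cue_onset_ms)) s$cue_onset_ms <- NA_integer_
  int_cols <- c("trial_id", "central_onset_ms", "central_offset_ms",
                "peripheral_onset_ms", "peripheral_offset_ms", "cue_onset_ms",
                "session_start_ms")
  for (nm in int_cols) s[[nm]] <- as.integer(s[[nm]])
  s <- s[c(need[1:7], "cue_onset_ms", "session_start_ms")[
    c(1:7, 8, 9)]]
  s <- s[, c("trial_id", "condition", "central_onset_ms", "central_offset_ms",
             "peripheral_onset_ms", "peripheral_offset_ms", "target_side",
             "cue_onset_ms", "session_start_ms")]
  class(s) <- c("trial_schedule", "data.frame")
  s
}
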