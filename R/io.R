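GAZE_COLS <- c("participant_id", "group", "trial_id", "time_ms", "x_deg",
               "y_deg", "pupil_mm", "valid")

#' Read a tab-separated gaze table
#'
#' The on-disk format is a TSV with a header row and columns
#' `participant_id, group, trial_id, time_ms, x_deg, y_deg, pupil_mm, valid`
#' (`valid` is 0/1; positions and pupil of invalid samples are sentinels,
#' read back as `NA`). Rows are sorted by participant, trial, and time.
#' Strict mode rejects duplicate or non-monotone timestamps within a trial;
#' lenient mode drops the offending rows with a warning.
#'
#' @param path file path.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A gaze-table `data.frame` with logical `valid`.
#' @export
read_gaze_table <- function(path, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  d <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  miss <- setdiff(GAZE_COLS, names(d))
  if (length(miss))
    stop("schema error: missing column '", miss[1], "'", call. = FALSE)
  d <- d[GAZE_COLS]
  if (!all(d$valid %in% c(0L, 1L)))
    stop("schema error: valid must be 0/1", call. = FALSE)
  d$valid <- d$valid == 1L
  d <- d[order(d$participant_id, d$trial_id, d$time_ms), , drop = FALSE]
  key <- paste(d$participant_id, d$trial_id)
  dup <- duplicated(cbind(key, d$time_ms))
  if (any(dup)) {
    if (mode == "strict")
      stop("monotonicity violation: duplicated timestamp within a trial ",
           "(participant ", d$participant_id[which(dup)[1]], ", trial ",
           d$trial_id[which(dup)[1]], ")", call. = FALSE)
    warning("dropped ", sum(dup), " row(s) with duplicated timestamps",
            call. = FALSE)
    d <- d[!dup, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' @rdname read_gaze_table
#' @param gaze a gaze-table data frame.
#' @export
write_gaze_table <- function(gaze, path) {
  out <- gaze[GAZE_COLS]
  out$valid <- as.integer(out$valid)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

pipeline_config <- function(config = NULL) {
  cfg <- list(task = task_config(), aois = aoi_set(), ivt = ivt_config(),
              pupil = pupil_config(), min_valid_trials = 4L)
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

#' Run the full gap-overlap analysis pipeline
#'
#' Orchestrates the stages in order: schedule validation, trial-metric and
#' pupil extraction, latency exclusions, MAD outlier removal, per-measure
#' participant retention, and the three trial-level mixed models with their
#' contrast tables and the per-group pupil/no-shift odds ratios. All result
#' tables plus a machine-readable run manifest are written to `out_dir`;
#' identical inputs and seed give byte-identical outputs. Results are
#' computed fully in memory before anything is written, so a failing stage
#' leaves no partial outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (used by simulation mode).
#' @param gaze,schedules input gaze table and stacked schedules; omit both
#'   and supply `simulate` instead.
#' @param simulate optional list `list(n_per_group =, truth =)` to simulate
#'   the cohort instead of reading one.
#' @param config optional list overriding pipeline components (`task`,
#'   `aois`, `ivt`, `pupil`, `min_valid_trials`).
#' @return Invisibly, a results bundle: trial outcomes, retention reports,
#'   exclusion tallies, model summaries, contrast tables, odds ratios, and
#'   the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1L, gaze = NULL, schedules = NULL,
                         simulate = NULL, config = NULL) {
  cfg <- pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(simulate)) {
    sim <- stage("simulate", {
      truth <- simulate$truth %||% simulation_truth()
      simulate_cohort(simulate$n_per_group, truth, seed = seed,
                      config = cfg$task, aois = cfg$aois)
    })
    gaze <- sim$gaze
    schedules <- sim$schedules
  } else sim <- NULL
  if (is.null(gaze) || nrow(gaze) == 0L)
    stop("stage 'input' failed: empty gaze table", call. = FALSE)
  if (is.null(schedules) || nrow(schedules) == 0L)
    stop("stage 'input' failed: no schedules", call. = FALSE)
  stage("validate_schedule", {
    for (pid in unique(schedules$participant_id)) {
      viol <- validate_schedule(
        schedules[schedules$participant_id == pid, , drop = FALSE],
        cfg$task)
      if (nrow(viol))
        stop("participant ", pid, ": ", nrow(viol),
             " schedule violation(s), first: trial ", viol$trial_id[1],
             " [", viol$rule[1], "]")
    }
  })
  outcomes <- stage("trial_metrics",
                    compute_trial_outcomes(gaze, schedules, cfg$aois,
                                           cfg$pupil))
  excl <- stage("latency_exclusions", apply_latency_exclusions(outcomes))
  outcomes <- excl$outcomes
  retention <- stage("retention", {
    do.call(rbind, lapply(c("latency", "noshift", "pupil"), function(m)
      min_valid_trials_filter(outcomes, cfg$min_valid_trials, m)$report))
  })
  keep_for <- function(measure) {
    ids <- retention$participant_id[retention$measure == measure &
                                      retention$retained]
    outcomes[outcomes$participant_id %in% ids, , drop = FALSE]
  }
  models <- stage("stats", {
    lat <- fit_latency_lmm(keep_for("latency"))
    ns <- fit_noshift_lmm(keep_for("noshift"))
    pup_data <- keep_for("pupil")
    pup <- fit_pupil_lmm(pup_data[pup_data$condition != "gap", ,
                                  drop = FALSE])
    ors <- suppressWarnings(fit_glmm_noshift_on_pupil(keep_for("pupil")))
    list(latency = lat, noshift = ns, pupil = pup, odds_ratios = ors)
  })
  contrasts <- stage("contrasts", {
    lapply(models[c("latency", "noshift", "pupil")], function(m) {
      list(within_group = if (m$has_group)
        marginal_means_and_contrasts(m, "by_condition_within_group") else
          marginal_means_and_contrasts(m, "overall"),
        between_group = if (m$has_group)
          marginal_means_and_contrasts(m, "by_group_within_condition"),
        contrast_of_contrasts = if (m$has_interaction)
          contrast_of_contrasts(m))
    })
  })
  noshift_summary <- summarize_noshift(outcomes)
  # ---- write everything at once ----
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name)
    data.table::fwrite(as.data.frame(x), file.path(out_dir, name))
  wr(outcomes, "trial_outcomes.csv")
  wr(retention, "retention.csv")
  wr(excl$tally, "exclusion_tally.csv")
  wr(noshift_summary, "noshift_summary.csv")
  if (!is.null(sim)) wr(sim$truth_table, "ground_truth.csv")
  for (nm in c("latency", "noshift", "pupil")) {
    wr(models[[nm]]$omnibus, paste0(nm, "_omnibus.csv"))
    wr(models[[nm]]$fixed_effects, paste0(nm, "_fixed_effects.csv"))
    wr(contrasts[[nm]]$within_group$contrasts,
       paste0(nm, "_contrasts_within_group.csv"))
    if (!is.null(contrasts[[nm]]$between_group))
      wr(contrasts[[nm]]$between_group$contrasts,
         paste0(nm, "_contrasts_between_group.csv"))
    if (!is.null(contrasts[[nm]]$contrast_of_contrasts))
      wr(contrasts[[nm]]$contrast_of_contrasts$contrasts,
         paste0(nm, "_contrast_of_contrasts.csv"))
  }
  wr(models$odds_ratios, "noshift_pupil_odds_ratios.csv")
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(package = "gapeyetrack",
                   version = as.character(utils::packageVersion("gapeyetrack")),
                   seed = seed,
                   simulated = !is.null(sim),
                   n_participants = length(unique(schedules$participant_id)),
                   n_trials = nrow(schedules),
                   config_hash = unname(tools::md5sum(tmp)),
                   config = cfg)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  bundle <- list(trial_outcomes = outcomes, retention = retention,
                 exclusion_tally = excl$tally,
                 noshift_summary = noshift_summary, models = models,
                 contrasts = contrasts, manifest = manifest,
                 simulation = sim)
  invisible(bundle)
}
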