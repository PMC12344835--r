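#' @importFrom lmerTest lmer
#' @importFrom lme4 glmer fixef VarCorr isSingular
NULL

as_model_factors <- function(d) {
  d$condition <- factor(d$condition,
                        levels = intersect(CONDITIONS, unique(d$condition)))
  d$group <- factor(d$group)
  d$participant_id <- factor(d$participant_id)
  d
}

check_full_grid <- function(d) {
  if (nlevels(d$group) > 1L) {
    tab <- table(d$group, d$condition)
    if (any(tab == 0L)) {
      cell <- which(tab == 0L, arr.ind = TRUE)[1L, ]
      stop("singular-design error: no trials in cell group '",
           rownames(tab)[cell[1]], "' x condition '",
           colnames(tab)[cell[2]], "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

fit_trial_lmm <- function(d, response, kind, backtransform) {
  check_full_grid(d)
  rhs <- if (nlevels(d$group) > 1L) "condition * group" else "condition"
  degenerate_response <- stats::var(d[[response]]) < 1e-12
  if (nlevels(d$participant_id) < 2L || degenerate_response) {
    warning(if (degenerate_response)
      "degenerate response: zero variance; fitting a fixed-effects model" else
        paste0("degenerate design: fewer than two participants; fitting a ",
               "fixed-effects model without a participant intercept"),
      call. = FALSE)
    fit <- stats::lm(stats::as.formula(paste(response, "~", rhs)), data = d)
    omni <- as.data.frame(stats::anova(fit))
    omni <- data.frame(term = rownames(omni), F = omni$`F value`,
                       df_num = omni$Df,
                       df_den = omni$Df[nrow(omni)], p = omni$`Pr(>F)`,
                       stringsAsFactors = FALSE)
    omni <- omni[omni$term != "Residuals", ]
    fe <- as.data.frame(coef(summary(fit)))
    fe <- data.frame(term = rownames(fe), estimate = fe[, 1], SE = fe[, 2],
                     df = stats::df.residual(fit), t = fe[, 3], p = fe[, 4],
                     stringsAsFactors = FALSE)
    rv <- data.frame(grp = "Residual", var = stats::sigma(fit)^2)
  } else {
    fml <- stats::as.formula(paste(response, "~", rhs,
                                   "+ (1 | participant_id)"))
    # Satterthwaite machinery can fail on degenerate fits (e.g. a constant
    # response); fall back to the plain lme4 fit with residual df then.
    fit <- tryCatch(lmerTest::lmer(fml, data = d, REML = TRUE),
                    error = function(e) lme4::lmer(fml, data = d,
                                                   REML = TRUE))
    a <- if (inherits(fit, "lmerModLmerTest"))
      tryCatch(as.data.frame(stats::anova(fit, type = 3)),
               error = function(e) NULL) else NULL
    if (is.null(a) || !"Pr(>F)" %in% names(a)) {
      # documented fallback when the Satterthwaite approximation is
      # unavailable: residual degrees of freedom
      a0 <- as.data.frame(stats::anova(fit, ddf = "lme4"))
      ddf <- nrow(d) - length(lme4::fixef(fit))
      a <- data.frame(`F value` = a0$`F value`, NumDF = a0$npar %||% a0$Df,
                      DenDF = ddf, check.names = FALSE)
      a$`Pr(>F)` <- stats::pf(a$`F value`, a$NumDF, a$DenDF,
                              lower.tail = FALSE)
      rownames(a) <- rownames(a0)
      attr(a, "ddf_method") <- "residual"
    }
    omni <- data.frame(term = rownames(a), F = a$`F value`,
                       df_num = a$NumDF, df_den = a$DenDF, p = a$`Pr(>F)`,
                       stringsAsFactors = FALSE)
    fe <- as.data.frame(coef(summary(fit)))
    if (!"df" %in% names(fe)) {
      fe$df <- nrow(d) - length(lme4::fixef(fit))
      fe$`Pr(>|t|)` <- 2 * stats::pt(-abs(fe$`t value`), fe$df)
    }
    fe <- data.frame(term = rownames(fe), estimate = fe[, "Estimate"],
                     SE = fe[, "Std. Error"], df = fe[, "df"],
                     t = fe[, "t value"], p = fe[, "Pr(>|t|)"],
                     stringsAsFactors = FALSE)
    rv <- as.data.frame(lme4::VarCorr(fit))[, c("grp", "vcov")]
    names(rv) <- c("grp", "var")
    if (lme4::isSingular(fit))
      warning("singular random-effects fit (a variance component is zero)",
              call. = FALSE)
  }
  if (stats::sigma(fit) < 1e-8)
    warning("zero residual variance: the response is degenerate",
            call. = FALSE)
  out <- list(kind = kind, fit = fit,
              formula = paste(response, "~", rhs,
                              if (inherits(fit, "merMod"))
                                "+ (1 | participant_id)" else ""),
              fixed_effects = fe, omnibus = omni, random_variances = rv,
              backtransform = backtransform,
              has_group = nlevels(d$group) > 1L,
              has_interaction = nlevels(d$group) > 1L,
              n_obs = nrow(d))
  class(out) <- "gaze_model"
  out
}

#' @export
print.gaze_model <- function(x, ...) {
  cat("Trial-level mixed model (", x$kind, ")\n", sep = "")
  cat("  ", x$formula, "   [n = ", x$n_obs, "]\n", sep = "")
  cat("Omnibus tests:\n")
  print(x$omnibus, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit the trial-level gaze-shift latency mixed model
#'
#' Natural-log latency modelled with condition-by-group fixed effects and a
#' participant random intercept, fitted by REML; omnibus F-tests use
#' Satterthwaite denominator degrees of freedom (with a documented
#' residual-df fallback). Only valid shifted trials (no exclusion, positive
#' latency) enter the fit. With a single group the model reduces to
#' condition-only.
#'
#' @param trials trial-outcome data frame with `participant_id`, `group`,
#'   `condition`, `latency_ms`, and (optionally) `shifted`, `exclusion`.
#' @return A `gaze_model` with fixed effects, omnibus tests, and random
#'   effect variances; latency contrasts derived from it back-transform to
#'   ratios of ms.
#' @export
fit_latency_lmm <- function(trials) {
  d <- trials
  if (!is.null(d$exclusion)) d <- d[d$exclusion == "none", , drop = FALSE]
  if (!is.null(d$shifted)) d <- d[!is.na(d$shifted) & d$shifted, ,
                                  drop = FALSE]
  d <- d[!is.na(d$latency_ms) & d$latency_ms > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid latency trials", call. = FALSE)
  d <- as_model_factors(d)
  d$log_latency <- log(d$latency_ms)
  fit_trial_lmm(d, "log_latency", "latency", backtransform = TRUE)
}

#' Fit the trial-level no-shift mixed model
#'
#' The default is a linear probability model in percentage units: the
#' response is `100 x` the trial's no-shift indicator, with
#' condition-by-group fixed effects and a participant random intercept, so
#' cell means are mean no-shift percentages. `mode = "binomial"` instead
#' fits a logistic GLMM on the binary indicator.
#'
#' @param trials trial-outcome data frame (non-excluded trials with a known
#'   shift flag are used).
#' @param mode `"lpm"` (percentage-unit linear mixed model, default) or
#'   `"binomial"`.
#' @return A `gaze_model`.
#' @export
fit_noshift_lmm <- function(trials, mode = c("lpm", "binomial")) {
  mode <- match.arg(mode)
  d <- trials
  if (!is.null(d$exclusion)) d <- d[d$exclusion == "none", , drop = FALSE]
  d <- d[!is.na(d$shifted), , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable trials", call. = FALSE)
  d <- as_model_factors(d)
  if (mode == "lpm") {
    d$noshift_pct <- 100 * as.numeric(!d$shifted)
    fit_trial_lmm(d, "noshift_pct", "noshift", backtransform = FALSE)
  } else {
    check_full_grid(d)
    d$noshift <- as.numeric(!d$shifted)
    rhs <- if (nlevels(d$group) > 1L) "condition * group" else "condition"
    fit <- lme4::glmer(stats::as.formula(
      paste("noshift ~", rhs, "+ (1 | participant_id)")),
      data = d, family = stats::binomial())
    fe <- as.data.frame(coef(summary(fit)))
    fe <- data.frame(term = rownames(fe), estimate = fe[, 1], SE = fe[, 2],
                     df = NA_real_, t = fe[, 3], p = fe[, 4],
                     stringsAsFactors = FALSE)
    out <- list(kind = "noshift_binomial", fit = fit,
                formula = paste("noshift ~", rhs, "+ (1 | participant_id)"),
                fixed_effects = fe, omnibus = NULL,
                random_variances = as.data.frame(lme4::VarCorr(fit)),
                backtransform = FALSE,
                has_group = nlevels(d$group) > 1L,
                has_interaction = nlevels(d$group) > 1L, n_obs = nrow(d))
    class(out) <- "gaze_model"
    out
  }
}

#' Fit the phasic pupil-dilation mixed model
#'
#' Baseline-corrected pupil amplitude (mm) with condition-by-group fixed
#' effects and a participant random intercept. The model is defined only on
#' the two overlap conditions, which are visually identical; passing gap
#' trials is a contract error.
#'
#' @param trials trial-outcome data frame restricted to
#'   `overlap_silent`/`overlap_cued`; only rows with `pupil_valid`
#'   amplitudes are used.
#' @return A `gaze_model`.
#' @export
fit_pupil_lmm <- function(trials) {
  if (any(trials$condition == "gap"))
    stop("contract error: the pupil model is defined on the overlap ",
         "conditions only; remove gap trials", call. = FALSE)
  d <- trials[!is.na(trials$pupil_amplitude_mm), , drop = FALSE]
  if (!is.null(d$pupil_valid)) d <- d[d$pupil_valid, , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid pupil amplitudes", call. = FALSE)
  d$latency_ms <- NULL
  d <- as_model_factors(d)
  fit_trial_lmm(d, "pupil_amplitude_mm", "pupil", backtransform = FALSE)
}

emm_of <- function(model, spec) {
  fit <- model$fit
  if (inherits(fit, "merMod"))
    emmeans::emmeans(fit, spec, lmer.df = "satterthwaite",
                     lmerTest.limit = 1e7)
  else emmeans::emmeans(fit, spec)
}

# emmeans falls back to asymptotic z tests when Satterthwaite is unavailable;
# normalize either summary layout to (estimate, SE, df, t, p).
tidy_emm_summary <- function(cs) {
  if (is.null(cs$t.ratio)) {
    cs$t.ratio <- cs$z.ratio
    cs$df <- Inf
    cs$z.ratio <- NULL
  }
  cs
}

#' Estimated marginal means and Bonferroni-adjusted pairwise contrasts
#'
#' Marginal means on the model scale (log-ms for the latency model) over the
#' requested grid, with pairwise contrasts Bonferroni-adjusted within each
#' family; the family is the set of contrasts sharing one `by` level
#' (e.g. all pairwise group comparisons within one condition). Latency
#' contrasts are additionally back-transformed to ratios of ms.
#'
#' @param model a `gaze_model`.
#' @param scope `"by_condition_within_group"` (condition contrasts within
#'   each group), `"by_group_within_condition"` (group contrasts within each
#'   condition), or `"overall"` (condition contrasts averaged over groups).
#' @return A list of class `gaze_contrasts`: `means`, `contrasts` (with
#'   `p_adjusted` and `family_size`), `scope`.
#' @export
marginal_means_and_contrasts <- function(model,
                                         scope = c("by_condition_within_group",
                                                   "by_group_within_condition",
                                                   "overall")) {
  stopifnot(inherits(model, "gaze_model"))
  scope <- match.arg(scope)
  if (scope != "overall" && !model$has_group)
    stop("contract error: scope '", scope, "' references factor 'group', ",
         "absent from the model", call. = FALSE)
  spec <- switch(scope,
                 overall = ~condition,
                 by_condition_within_group = ~condition | group,
                 by_group_within_condition = ~group | condition)
  emm <- suppressMessages(emm_of(model, spec))
  cons <- emmeans::contrast(emm, method = "pairwise", adjust = "bonferroni")
  means <- as.data.frame(summary(emm))
  cs <- tidy_emm_summary(as.data.frame(summary(cons)))
  by_col <- setdiff(names(cs), c("contrast", "estimate", "SE", "df",
                                 "t.ratio", "p.value"))
  fam <- if (length(by_col)) stats::ave(cs$estimate, cs[by_col],
                                        FUN = length) else nrow(cs)
  out_cs <- data.frame(label = if (length(by_col))
    paste(cs$contrast, "|", cs[[by_col[1]]]) else as.character(cs$contrast),
    estimate = cs$estimate, SE = cs$SE, df = cs$df,
    t = cs$t.ratio, p_adjusted = cs$p.value,
    family_size = as.integer(fam), stringsAsFactors = FALSE)
  if (isTRUE(model$backtransform)) out_cs$ratio <- exp(out_cs$estimate)
  structure(list(means = means, contrasts = out_cs, scope = scope),
            class = "gaze_contrasts")
}

#' @export
print.gaze_contrasts <- function(x, ...) {
  cat("Marginal-mean contrasts (scope: ", x$scope, ")\n", sep = "")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Contrast-of-contrasts: do condition effects differ between groups?
#'
#' Differences between groups of within-group condition contrasts (e.g. the
#' gap-vs-overlap effect in one group minus the same effect in another),
#' with standard errors from the model covariance and Bonferroni adjustment
#' over the family of such comparisons. Defined only on the full
#' condition-by-group interaction model.
#'
#' @param model a `gaze_model` fitted with the interaction.
#' @return A list of class `gaze_contrasts`.
#' @export
contrast_of_contrasts <- function(model) {
  stopifnot(inherits(model, "gaze_model"))
  if (!isTRUE(model$has_interaction))
    stop("contract error: contrast_of_contrasts requires the full ",
         "condition x group interaction model", call. = FALSE)
  emm <- suppressMessages(emm_of(model, ~condition * group))
  cc <- emmeans::contrast(emm, interaction = "pairwise",
                          adjust = "bonferroni")
  cs <- tidy_emm_summary(as.data.frame(summary(cc)))
  out_cs <- data.frame(
    label = paste(cs[[1]], "x", cs[[2]]),
    estimate = cs$estimate, SE = cs$SE, df = cs$df, t = cs$t.ratio,
    p_adjusted = cs$p.value, family_size = nrow(cs),
    stringsAsFactors = FALSE)
  if (isTRUE(model$backtransform)) out_cs$ratio <- exp(out_cs$estimate)
  structure(list(means = as.data.frame(summary(emm)), contrasts = out_cs,
                 scope = "contrast_of_contrasts"),
            class = "gaze_contrasts")
}

#' Per-group odds ratios: does pupil dilation predict no-shift?
#'
#' For each group separately, a logistic generalized linear mixed model of
#' the trial-level no-shift indicator on the trial's phasic pupil amplitude
#' with a participant random intercept (Laplace approximation), restricted
#' to overlap-cued trials. The odds ratio is per 1 mm of dilation, with a
#' Wald 95% confidence interval; p-values are Bonferroni-adjusted across
#' the number of groups tested. A group with no (or only) no-shift events
#' yields a separation warning and a non-estimable row.
#'
#' @param trials trial-outcome data frame; rows are restricted to
#'   `condition == "overlap_cued"` with valid pupil amplitudes and a known
#'   shift flag.
#' @return A data frame of class `noshift_or`: `group`, `OR`, `CI95_low`,
#'   `CI95_high`, `SE_log_odds`, `p`, `p_adjusted`, `n_trials`.
#' @export
fit_glmm_noshift_on_pupil <- function(trials) {
  d <- trials[trials$condition == "overlap_cued", , drop = FALSE]
  if (!is.null(d$exclusion)) d <- d[d$exclusion == "none", , drop = FALSE]
  if (!is.null(d$pupil_valid)) d <- d[d$pupil_valid, , drop = FALSE]
  d <- d[!is.na(d$shifted) & !is.na(d$pupil_amplitude_mm), , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable overlap-cued trials", call. = FALSE)
  groups <- unique(d$group)
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    dg <- d[d$group == groups[i], , drop = FALSE]
    y <- as.numeric(!dg$shifted)
    row <- data.frame(group = groups[i], OR = NA_real_, CI95_low = NA_real_,
                      CI95_high = NA_real_, SE_log_odds = NA_real_,
                      p = NA_real_, p_adjusted = NA_real_,
                      n_trials = nrow(dg), stringsAsFactors = FALSE)
    if (all(y == 0) || all(y == 1)) {
      warning("group ", groups[i], ": no variation in the no-shift ",
              "response (separation); odds ratio not estimable",
              call. = FALSE)
      rows[[i]] <- row
      next
    }
    n_distinct <- tapply(dg$pupil_amplitude_mm, dg$participant_id,
                         function(x) length(unique(x)))
    if (all(n_distinct <= 1L))
      stop("rank-deficiency error: pupil amplitude is constant within ",
           "every participant in group ", groups[i], call. = FALSE)
    fit <- suppressMessages(lme4::glmer(
      y ~ pupil_amplitude_mm + (1 | participant_id),
      data = cbind(dg, y = y), family = stats::binomial()))
    b <- lme4::fixef(fit)[["pupil_amplitude_mm"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[[2]]
    row$OR <- exp(b)
    row$CI95_low <- exp(b - stats::qnorm(0.975) * se)
    row$CI95_high <- exp(b + stats::qnorm(0.975) * se)
    row$SE_log_odds <- se
    row$p <- 2 * stats::pnorm(-abs(b / se))
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * length(groups))
  class(out) <- c("noshift_or", "data.frame")
  out
}
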