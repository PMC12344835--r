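---
title: "Analysing gap-overlap eye-tracking sessions with gapeyetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing gap-overlap eye-tracking sessions with gapeyetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the measures

The gap-overlap paradigm measures how quickly gaze disengages from a fixated
stimulus. A central stimulus is shown for 800-1700 ms; a peripheral target
then appears for 1000 ms, either after the central stimulus has vanished for
a 120-200 ms blank *gap* or while it remains on screen (*overlap*). On
overlap-*cued* trials an auditory alerting cue precedes the target by
0-500 ms, engaging the phasic arousal (locus coeruleus-noradrenergic)
system, whose activity is indexed by cue-evoked pupil dilation. The default
session is 58 trials, split 21/18/19 across gap, overlap-silent and
overlap-cued.

Four quantities are derived per trial:

* **gaze-shift latency** — the time from peripheral-target onset to the
  first valid gaze sample inside the target-side area of interest (AOI);
* **shift / no-shift** — whether gaze ever left the central AOI for a
  peripheral AOI during the target window;
* **pupil baseline** — the median filtered pupil diameter in the
  1000-666 ms interval before target onset;
* **phasic dilation amplitude** — the median diameter in the 0-1500 ms
  response window minus the baseline.

The *gap effect* (overlap minus gap latency) indexes disengagement cost;
the *cue effect* (cued minus silent overlap) indexes phasic alerting.

## Processing rules and their boundaries

The pipeline applies the field's standard rules, each with an exact,
documented boundary:

* **I-VT event detection**: angular speed is the displacement between the
  valid samples nearest the edges of a 20 ms window centred on each sample,
  divided by their separation; samples strictly above 30 deg/s are saccade
  samples. A run at exactly the threshold is a fixation (ties break towards
  fixation, the common I-VT convention). Angular distance is Euclidean in
  degree coordinates — the small-angle approximation appropriate for inputs
  already expressed in degrees. At trace ends the window is truncated, never
  extrapolated. Fixations shorter than 60 ms lying strictly between two
  saccades are absorbed into the saccade (set `min_fixation_ms = 0` to
  disable).
* **Latency exclusions**: latencies strictly below 100 ms are anticipatory,
  strictly above 1000 ms improbable; the boundary values 100 and 1000 are
  kept. The 1000 ms bound is a fixed constant, not a recomputed percentile.
* **Retention**: for each outcome measure separately, a participant is kept
  only if all three conditions hold at least 4 valid trials (4/4/4 is kept).
* **Pupil preprocessing**: invalid runs strictly shorter than 100 ms and
  bounded by valid samples are linearly interpolated; an 80 ms moving median
  follows; trials with under 30% valid samples across the baseline and
  response windows give no amplitude; per participant, amplitudes farther
  than 3 x 1.4826 x MAD from the median are removed (nothing is removed when
  the MAD is exactly 0). All windows are closed on the left, open on the
  right, in trial-local milliseconds. The stage order
  interpolate -> filter -> amplitude is enforced by the objects themselves.

Two conventions were genuinely open and are package decisions: latency is
clocked from peripheral-stimulus onset in *every* condition (so the
gap/overlap contrast is purely a display property), and a first saccade to
the wrong side counts as a shift for the no-shift measure but contributes no
latency. The "on central at onset" gate requires at least half of the valid
samples in the 100 ms before onset to fall in the central AOI. The baseline
interval is implemented literally as [-1000, -666) ms before target onset
(334 ms of samples); it is anchored to target onset for all trials so that
it precedes every possible cue onset (maximum lead 500 ms < 666 ms). No-shift
denominators exclude anticipatory/improbable trials from both numerator and
denominator, so shifted + no-shift + excluded partitions every cell.

AOI geometry is configurable; the defaults are a 4 x 4 degree central AOI at
fixation and 6 x 6 degree peripheral AOIs at +/-10 degrees, a typical layout
for this display. Screen-to-degree conversion is the data producer's
responsibility.

## The statistical layer

All inference is at trial level with a participant random intercept, fitted
by REML via `lme4`/`lmerTest`:

* latency: natural-log latency ~ condition x group; contrasts are
  back-transformed to ratios of ms (the natural log makes the ratios
  base-free);
* no-shift: a linear probability model on 100 x the no-shift indicator, so
  coefficients are percentage units — the reading consistent with
  trial-level degrees of freedom in the thousands; a binomial GLMM is
  available as `mode = "binomial"`;
* pupil: amplitude (mm) ~ condition x group on the two overlap conditions
  only, which are visually identical (passing gap trials is an error);
* arousal-disengagement coupling: per group, a logistic GLMM (Laplace
  approximation) of the no-shift indicator on the trial's pupil amplitude,
  overlap-cued trials only, reported as an odds ratio per mm with a Wald 95%
  interval.

Denominator degrees of freedom use the Satterthwaite approximation
(`lmerTest`, and `lmer.df = "satterthwaite"` for `emmeans`, with the size
limit lifted so large trial-level fits do not silently fall back to
asymptotic tests). When the approximation is unavailable — e.g. a degenerate
fit — the code falls back to residual degrees of freedom and labels the
output. Follow-up comparisons are estimated marginal means with Bonferroni
adjustment; the family is the set of contrasts sharing one `by` level (all
pairwise group comparisons within a condition form one family, the three
condition comparisons within a group another). Contrast-of-contrasts
(whether a condition effect differs between groups) come from pairwise
interaction contrasts of the full model and require the interaction to be
present. The calibration of this machinery is itself under test: under a
null generator the omnibus F-tests and the Bonferroni families must reject
at close to the nominal 5% level.

## What the simulator emulates

`simulation_truth()` defines a complete generating model so that every stage
can be verified by parameter recovery:

* latencies are lognormal per group x condition
  (`log L = meanlog + u_i + e`); defaults place the typically developed
  adult gap median at 270 ms, overlap conditions ~19-24% slower, and
  developmentally delayed groups 25% slower — mirroring the published effect
  structure of the paradigm. Trial-level `sdlog` is 0.25 and the
  between-participant intercept sd 0.10, typical values for saccadic
  reaction times;
* the no-shift probability of each trial follows a logistic model whose
  linear predictor includes the trial's *true* phasic amplitude
  (default slope log 5 per mm, centred at the cell mean), coupling arousal
  and disengagement at trial level exactly as the odds-ratio analysis
  assumes;
* the pupil trace is a participant baseline (3.2 +/- 0.45 mm) plus the true
  amplitude times a peak-normalised gamma kernel
  `(t/tp)^s exp(s(1 - t/tp))` with latency-to-peak 930 ms and shape 10.1 —
  the standard pupillometry impulse response — time-locked to the cue on
  cued trials and to target onset otherwise, plus slow sinusoidal drift and
  white noise. Mean peak amplitudes default to 0.09 mm (cued) versus
  0.03 mm (silent/gap), with trial-level sd 0.15 mm and participant sd
  0.03 mm, in the range reported for cue-evoked dilations;
* the saccade is a constant-velocity transit (300 deg/s), timed so gaze
  crosses the target-AOI boundary exactly at `onset + latency`. The drawn
  latency is therefore *defined* as the AOI-entry latency — the quantity the
  extraction stage measures — rather than the saccade-onset time, which
  would differ by the transit time to the AOI edge and make exact noiseless
  recovery impossible;
* dropout is a boolean-model process: geometric runs (mean 60 ms) placed
  uniformly at a rate chosen so the stationary invalid fraction equals
  `dropout_rate`; blinks null both gaze and pupil channels;
* one global seed spawns per-participant and per-trial sub-streams, and all
  trial-level draws precede any rate-dependent draw, so the trial-level
  ground truth is bit-identical at 120 and 1200 Hz.

The simulator does **not** emulate fixational microsaccades and drift beyond
Gaussian noise, video-based pupil artefacts, luminance responses, corrective
saccades, or wrong-direction first saccades. Passing recovery tests
therefore shows the pipeline is a correct implementation of its rules under
the assumed generating model, not that the model captures every property of
real recordings.

Because the measured amplitude is a *window median* of the kernel rather
than its peak, trace-level amplitudes are attenuated by a known factor
(roughly 0.5-0.6 at the default kernel and cue leads); the trial-level
generator (`simulate_trial_table()`), which draws measured amplitudes
directly, is the reference for statistical recovery, while the trace-level
generator is checked against numerically computed kernel-window medians.

## Numerical and design choices

* Timing draws are uniform over the stated intervals, in integer
  milliseconds; trial order is a uniform permutation of the condition
  multiset; target sides are balanced within rounding with no run longer
  than 3 (redrawn, still under the seed, if the balance constraint corners
  the construction).
* Velocity and median windows use inclusive half-window membership with a
  1 ns tie guard; run durations count one nominal sample interval per
  sample, so events tile the trace exactly.
* Gap-run length for interpolation is the number of missing samples times
  the nominal interval; runs touching a trace end are never filled.
* The MAD consistency constant 1.4826 makes the 3 x MAD rule remove ~0.27%
  of Gaussian data; it is configurable.
* Degenerate inputs degrade with warnings, not crashes: single-participant
  or zero-variance responses fall back to fixed-effects fits, groups with
  no no-shift events report non-estimable odds ratios, and a constant
  predictor within every participant is a rank-deficiency error.

## Verification strategy and problem sizes

The test suite verifies, in increasing order of integration: exact printed
design constants; element-wise equality of every signal-processing stage
with naive brute-force references on random traces; exact rule boundaries
(95/100/1000/1001 ms latencies, 96 vs 100 ms gaps, 3 vs 4 valid trials,
30% pupil validity); noiseless end-to-end recovery (latencies within one
sample interval, amplitudes within 0.005 mm of the kernel-window median, at
both sampling rates); statistical recovery of generating effects (condition
log-ratio 1.20 within 0.02, group ratio 1.25 within 0.05, pupil contrast
0.06 mm within 0.01 mm, with the median over five replicate cohorts of 40
participants per group; odds ratio 5 per mm with the median over 200
replicate GLMM fits in [3.5, 7]); and null calibration (rejection rates in
[0.03, 0.07] over 500 replicates of 24-participant cohorts). These problem
sizes keep the whole suite around two minutes while leaving each check
comfortably powered; the replicate-median is used for the single-cohort
recoveries so that a check's verdict reflects estimator accuracy rather
than one cohort's sampling noise.

## Known limitations

* The no-shift linear probability model inherits the usual LPM caveats
  (heteroscedastic, unbounded predictions); it is retained because
  percentage-unit coefficients with trial-level df match the analysis it
  implements, and the binomial mode is one argument away.
* Odds-ratio estimates from ~19 cued trials per participant carry
  substantial small-sample variability and mild Laplace bias; the recovery
  criterion is therefore stated on the median across replicates.
* Pupil traces recorded at a lower rate than gaze (e.g. 40 Hz devices) are
  handled by operating in continuous time on whatever samples exist — the
  window median is the median of available samples — rather than by
  resampling; results can differ from upsampling-based pipelines in edge
  cases.
* The baseline interval is stated in the literature both as "333 ms" and as
  the 1000-666 ms pre-onset interval; this implementation uses the interval
  [-1000, -666) literally.
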