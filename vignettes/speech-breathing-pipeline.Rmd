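---
title: "Linking respiration maxima to conversational speech onsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking respiration maxima to conversational speech onsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathturn)
```

## The problem

Before speaking, people take a short, rapid inhalation (roughly 200-500 ms)
and then produce speech on a prolonged exhalation. In conversation this
coupling is tight enough that the maximum of the respiratory cycle — the
inspiration-to-expiration transition measured by a respiration belt — tends
to precede the speaker's speech onset by about 200 ms. `breathturn`
implements the signal-processing and statistical chain needed to quantify
that coupling in recordings made during scanning sessions: it repairs belt
saturation, extracts respiration maxima, segments speech into inter-pausal
units (IPUs: stretches of continuous speech bounded by silences longer than
200 ms), labels each maximum as speech-associated (Resp+) or not (Resp-),
and characterises the distribution of the lag

\[
\Delta t = t_{\text{peak}} - t_{\text{IPU onset}},
\]

negative when the breath maximum precedes speech. The labelled maxima are
exported as zero-duration events in BIDS-style TSV, the boundary at which a
neuroimaging GLM would take over; nothing downstream of event export
(model estimation, maps) is in scope.

Because the corpora this kind of analysis is run on are not redistributable,
the package ships a synthetic-data generator with known ground truth so that
every stage is testable end to end.

## Pipeline stages

1. **Belt preprocessing** (`moving_average`, `detect_saturation`,
   `interpolate_gaps`, `resample_to_ms`, `align_to_session`,
   `detect_peaks`). The belt signal (200 Hz, arbitrary units) is screened
   for saturation plateaus — runs of identical extreme values where the
   sensor hit a measurement rail, typically during strong inspirations.
   Flagged runs are repaired, the trace is linearly resampled to 1 ms
   resolution, and aligned to the session clock using the known
   synchronisation between the end of the belt recording and the end of the
   scanning session (`origin = session_duration - trace_duration`). Maxima
   are then extracted with prominence and separation criteria.
2. **Speech segmentation** (`rms_envelope`, `threshold_from_rms`,
   `segment_ipus`). A per-participant threshold — a float coefficient
   (working range 0.20-0.95) times the mean of the RMS distribution —
   classifies frames as speech or silence; sub-threshold runs of at most
   200 ms are merged (the IPU definition splits only on pauses *longer*
   than 200 ms), and speech runs shorter than 100 ms are dropped as click
   artifacts (the pause rule defines pauses, not a minimum IPU length;
   100 ms is this package's choice).
3. **Event alignment** (`ipus_to_session_clock`, `classify_peaks`,
   `export_glm_events`). Block-relative IPU onsets are shifted by the block
   onsets from the session log. For every participant IPU onset the
   temporally closest maximum (absolute value) becomes Resp+; all
   never-linked maxima are Resp-. The labels partition the peak set; a peak
   closest to several onsets is a single Resp+ event but contributes one
   \(\Delta t\) record per IPU. There is deliberately no matching window —
   the nearest peak is Resp+ however far away — because extreme lags are
   handled downstream by the outlier filter. Ties between two equidistant
   peaks break toward the earlier peak (inhalation precedes speech).
4. **Lag statistics** (`remove_outliers_mad`, `ks_normality`,
   `skewness_test`, `density_mode`, `compare_conditions`,
   `summarize_deltas`). Outliers are values more than three scaled median
   absolute deviations from the median (scale constant 1.4826, the normal
   consistency constant used by common robust-outlier routines; an
   unscaled variant is available via `scale = "raw"`). Normality is tested
   with the Lilliefors-corrected Kolmogorov-Smirnov test, because the
   normal's parameters are estimated from the same data. Asymmetry uses
   the adjusted Fisher-Pearson skewness with D'Agostino's test. The lag
   distribution's mode is the argmax of a Gaussian KDE on a 1 ms grid.
5. **Sulcus tracing** (`find_seed`, `trace_sulcus`, `categorize_peak`,
   `tally_categories`). On a 2-D axial grayscale slice, the central sulcus
   is drawn by a greedy walk from a fundus seed: among the 8-neighbours not
   already on the path whose distance from the interhemispheric midline
   column is non-decreasing (1 px hysteresis), step to the lowest-intensity
   pixel; stop at the image border, a length cap, or when the best
   candidate exceeds a stop intensity (default: midpoint between the
   image's darkest level and its median). An activation peak is then
   categorised, in fixed order, as FUNDUS (closer than 1 px to the seed),
   ON_LINE (closer than 1 px to the traced line), else ANTERIOR/POSTERIOR
   by the sign of its projection onto the declared anterior axis.

`run_session()` chains the stages with on-disk TSV/JSON boundaries so any
stage can be replaced by external tooling, and `run_cohort()` pools lag
records across sessions both at the IPU level and at the level of
per-session means (the appropriate aggregation unit for the group test is
ambiguous in practice, so both are reported).

## The synthetic generator

`generate_conversation()` places non-overlapping IPUs on a shared timeline:
gamma-distributed utterance durations (mean 3 s), silences of mean 1 s with
a strict 0.2 s floor, stochastic speaker alternation. These defaults give
one participant IPU per ~8 s of conversation, matching the per-session
Resp+ counts reported for conversational corpora of this design.

`generate_respiration()` builds the belt waveform from piecewise raised
cosines: a fast rise over the inhalation (0.2-0.5 s) and a slow fall over
the exhalation (1.2-2.5 s; mean cycle ~2.2 s, i.e. ~210 maxima in a 464 s
session — the rate implied by the corpus the analysis is modelled on,
21,542 maxima over one hundred 463.925 s sessions). Only peak timing and
cycle asymmetry matter to the downstream analysis, so no physiological ODE
model is used. Speech-coupled maxima are placed at `onset + lag` with lags
drawn from a negated gamma (shape 6, sd 165 ms) shifted so its density
peaks at -200 ms — left-skewed with a short positive tail. All participant
onsets are coupled by default; onsets closer than one minimal exhalation to
the previous coupled peak lose their own peak (a shared-breath group),
leaving ~2-3% of onsets without a dedicated maximum. Metabolic maxima fill
the remaining time and are kept at least 1 s from every participant onset
so ground-truth labels are unambiguous; that clearance is a labelling
convenience, not a claim about real metabolic breathing, and it makes
uncoupled onsets' lags large by construction. Baseline wander (mean-reverting with a 60 s
time constant and a stationary sd of 5% of amplitude — belts drift, they do
not walk away, so the wander must not grow with recording length) and
white noise (1% of amplitude) ride on top of the clean waveform;
ground-truth peak times refer to the clean waveform.

What the generator does *not* emulate: overlapping speech, listener
(non-speaker) breathing adaptation, amplitude-phase coupling between
speech loudness and exhalation depth, scanner artifacts beyond rail
clipping, or any cardiac signal. Passing tests therefore demonstrate that
the chain recovers what this generative family produces — not that real
conversational data meet the same accuracy.

A fixed master seed drives everything: each generator call derives a child
stream via `child_seed()` (an affine map modulo \(2^{31}-1\)), so re-running
a configuration is byte-identical and adding a stage does not perturb the
others.

## Numerical and design choices

**Saturation detection.** The paper-style rule — runs of null derivative in
a 50-bin (250 ms) moving average, restricted to the top/bottom amplitude
decile so flat mid-range breathing pauses are not falsely repaired — finds
plateau *cores*. With sensor noise, the rail run fragments (samples dither
just below the rail), so cores are also taken from runs of identical raw
values, then grown through a rail neighbourhood of three robust noise
standard deviations and merged across sub-`min_run` gaps. The derivative
tolerance defaults to exactly zero for integer-quantised belts and
`1e-9` of the amplitude range for float input, since exact-zero tests are
fragile under smoothing in floating point.

**Repair.** Each flagged gap is bridged by a natural cubic regression
spline (knots every 50 ms at data quantiles, symmetric context at least as
wide as the gap). An *interpolating* spline through every noisy sample —
the obvious alternative — reproduces sample noise exactly and amplifies it
into overshoots of several tenths of the signal amplitude inside wide gaps;
the least-squares fit averages the noise instead, while samples outside the
flagged intervals are never modified. Gaps touching the signal ends are
filled by nearest-value hold rather than extrapolated. Repair of a trace
with no flagged intervals is the identity.

**Peak timing.** The breath maximum is a corner between a steep rise and a
gentle fall, and the argmax of any symmetrically smoothed copy of such a
peak is systematically late (the smoothing shifts mass toward the flatter
side) — 20-40 ms at this package's default noise level, enough to corrupt
a 200 ms lag estimate. The default estimator therefore works on the
inhalation upstroke: the derivative of the rise is a nearly symmetric bump
ending at the peak, so its centroid estimates the mid-rise without bias,
and the peak time is the centroid plus half the rise duration, recovered
from the bump's second moment (variance constants calibrated once against
the ideal half-sine upstroke, including the 10% support threshold and the
smoothing kernel). When the upstroke is cut off by the start of the trace
the estimator falls back to a local argmax. On clean synthetic sessions
this locates every maximum within a few milliseconds; peaks inside repaired
saturation gaps remain the dominant error source (tens of milliseconds,
biased late), an intrinsic cost of reconstructing a clipped extremum.

**Mode estimation.** `density_mode()` defaults to Silverman's bandwidth.
For *cohort-level* mode recovery the package uses a fixed 50 ms bandwidth
instead: the mode of a left-skewed lag density has a flat top, and at a few
thousand observations the Silverman-bandwidth argmax wanders by tens of
milliseconds, whereas the wider kernel trades that variance for a small,
known smoothing bias (about -7 ms toward the tail for the default lag
family) that partially cancels the late bias of repaired peaks.

**Group comparison.** Both pooled-variance and Welch t statistics are
reported; with near-equal spreads they agree. The comparison supports
pooling conditions when no difference is found.

**Conventions.** Sample intervals are 1-based inclusive `[start, end]`
integer pairs. Even moving-average windows centre on the leading sample (a
50-bin window covers `[i-25, i+24]`). Times are seconds on the session
clock. Sulcus coordinates are `(row, col)` matrix indices with the anterior
axis defaulting to +row under the package's declared slice orientation.

## Problem sizes and verification

The test suite and the acceptance script regenerate everything they check.
Cohort-scale checks use ten 3000 s synthetic sessions per lag mode
(~3,500 lag records per cohort) for mode recovery within ±25 ms at modes
of -300, -200 and -100 ms; classifier correctness is checked against an
exhaustive nearest-neighbour rule on random small instances; the saturation
detector and repairer are checked against analytic clipping of a unit sine;
the tracer against generated images at 10% noise. Single-session runs use
the scanning-session layout: 385 volumes at TR 1.205 s (463.925 s) holding
six one-minute conversation blocks, alternating human and robot
interlocutor labels.

## Known limitations

- Peaks reconstructed inside saturation gaps carry tens of milliseconds of
  timing error; the analysis tolerates this through the outlier filter and
  the width of the lag distribution, but per-event timing inside gaps
  should not be over-interpreted.
- The IPU segmenter assumes a denoised single-channel envelope; audio
  denoising itself is out of scope (the generator injects residual noise
  instead).
- The sulcus tracer is 2-D, single-slice, and greedy; it does not replace
  observer validation of the sulcus identification, and a poor seed or a
  broken dark band can stop the walk early.
- The per-participant RMS coefficient is taken as input; the original
  selection procedure for it is not specified, so a grid search against
  annotated IPUs is offered only as a convenience.
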