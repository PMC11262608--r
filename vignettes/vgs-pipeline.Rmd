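---
title: "Methods: visually guided saccade analysis and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visually guided saccade analysis and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgspipe)
```

## The measurement problem

A visually guided saccade (VGS) task probes the oculomotor system with a
sudden peripheral target. In the *gap paradigm* the central fixation dot
disappears 200 ms before the target appears, releasing fixation and
shortening latencies. Clinically, the interesting quantities are the
latency, amplitude, velocity and gain (amplitude / target eccentricity) of
the first target-directed saccade, the fraction of trials a patient can
perform validly, and the blink rate — all of which are altered in
Parkinson's disease (hypometric saccades, longer vertical latencies,
reduced spontaneous blink rate).

`vgspipe` implements the full chain from a raw binocular gaze export to
those quantities, plus a simulator that generates such recordings with
known ground truth so every stage can be tested without patient data.

## Screen geometry

Conversions assume a flat screen viewed orthogonally through its centre:
an offset of $p$ pixels corresponds to
$\theta = \arctan(p \cdot c / D)$ degrees, with $c$ the pixel pitch in
cm/px (from the diagonal, aspect ratio and horizontal resolution; square
pixels) and $D$ the viewing distance. The default display (23″, 16:9,
1920×1080, 65 cm) gives $c = 0.02652$ cm/px, so the 100-px trial start
radius is `r round(pixels_to_degrees(100), 2)`°. The same arithmetic is
used in reverse to place targets, and the angular distance between two
gaze points is the true angle between their eye rays (not the difference
of eccentricities), so oblique amplitudes are measured correctly.
Display latency (1–3.3 ms) and tracker accuracy (~0.4°) are carried as
metadata only; nothing downstream consumes them.

## The I-VT chain

Events are detected by velocity thresholding with the settings used for
the clinical recordings, in this order:

1. **Blink detection** on the *raw* validity codes: maximal runs where
   both eyes are invalid, lasting 50–500 ms, are blinks. The bounds are
   physiological defaults (shorter runs are data dropouts, longer ones
   tracking loss). A run with only one eye invalid is never a blink — the
   other eye still sees. Blink intervals are excised from the cyclopean
   trace *before* interpolation so a gap fill can never manufacture gaze
   positions through a blink.
2. **Eye averaging**: midpoint of the two eyes when both are valid, the
   valid eye alone otherwise, missing when neither.
3. **Gap-fill interpolation**: missing runs of ≤ 75 ms with valid samples
   on both flanks are linearly interpolated. A run of $k$ missing samples
   counts as $k$ sample periods.
4. **Windowed velocity**: at sample $i$, the angular distance between the
   samples at the ends of a 20 ms window centred on $i$, divided by their
   separation. At 250 Hz this means the samples two positions either side
   (16 ms apart). Where the full symmetric window does not fit — the
   first/last samples, and samples whose window endpoint is missing — the
   velocity is left undefined rather than computed over a shrunken
   window: halving the time base doubles the noise gain, and at realistic
   noise a 8 ms window misclassifies edge samples as saccadic more often
   than not.
5. **Classification**: $v \ge 30$ °/s ⇒ saccade, below ⇒ fixation,
   undefined ⇒ missing. All threshold comparisons in the chain are
   inclusive.
6. **Event assembly**: maximal runs of one label become events; missing
   runs become gaps; blink intervals override whatever the classifier
   said there. Event spans are half-open `[t_start, t_end)` and tile the
   recording exactly.
7. **Fixation merging**: adjacent fixations ≤ 75 ms apart with centroids
   ≤ 0.5° apart merge (span = union, centroid = duration-weighted mean),
   repeatedly until stable. Gap events *and saccade fragments* between the
   two fixations are absorbed — this is what removes the isolated
   supra-threshold samples that position noise produces — but a blink
   always blocks a merge. Merging runs before the duration filter (the
   conventional order for this filter family).
8. **Minimum fixation duration**: fixations < 60 ms become gaps.

The `noise_reduction` flag exists for configuration fidelity and is a
no-op, matching the recording settings (noise reduction disabled).

One wording in the source conventions deserves a flag: validity code 0
means *valid* ("high confidence") and nonzero means invalid, and blinks
are intervals where **both eyes are invalid**. Descriptions that read as
"validity indicated 0 during blinks" conflate the two; this package
implements both-eyes-invalid.

## Trial validity and saccadic parameters

Each trial is the slice `[central onset, target offset)`. The filter
applies three checks in order, recording the first failure:

 a. no saccade or blink event overlaps the 60 ms before central-dot
    offset (saccade checked first);
 b. gaze at central-dot offset lies within 100 px of the screen centre
    (a missing position is tracking loss). The instant of evaluation is
    the central-dot offset — the criterion describes the "starting point"
    the subject must hold before the target appears;
 c. the first saccade starting at/after target onset whose start position
    is within the 100-px radius begins within [100, 1500) ms of target
    onset. Below 100 ms it is anticipatory; the upper bound equals the
    target presentation time, so the saccade must begin while the target
    is visible (an unbounded latency would let post-target drift count as
    a response).

Latency, duration, amplitude (angular distance between the gaze positions
at saccade onset and offset — the full 2D displacement, not an axis
projection), mean/peak velocity over the saccade span, and gain are then
computed for the selected saccade. Velocities are reported in °/s
throughout. Aggregation groups valid trials by eccentricity class (near =
±10°, far = ±18°, up/down = ∓8° in screen-y convention) with sample SDs
(n−1); the ≥ 6 valid trials inclusion rule is applied per task, since the
two tasks are separate recordings that can fail independently.

The vertical protocol presents each of the two ±8° targets 20 times, so
both tasks comprise 40 presentations; the repetition count is a protocol
parameter for users who prefer 10.

## The simulator

The generator emulates the study conditions: 250 Hz binocular sampling of
the 1500/200/1500 ms gap protocol with randomized target order. Its
models and defaults, chosen once from oculomotor literature norms:

* **Main sequence** $V_p = v_{max}(1 - e^{-A/a_0})$ with
  $v_{max} = 600$ °/s, $a_0 = 8$° — the standard saturating
  amplitude–peak-velocity relationship for adult saccades.
* **Raised-cosine velocity profile** $v(t) = V_p(1-\cos 2\pi t/D)/2$,
  duration $D = 2A/V_p$; the position is the closed-form integral, so the
  sampled waveform spans exactly $A$ and the profile's time-mean velocity
  is exactly $V_p/2$.
* **Latency**: 130 ms shift + Gamma(shape 4, scale 25 ms) ⇒ mean ≈ 230 ms,
  SD ≈ 50 ms, typical of gap-paradigm VGS. Anticipatory saccades
  (probability 0.05) draw latency uniformly on [0, 100) ms, toward the
  correct target.
* **Gain**: Gaussian 0.9 ± 0.08 (mildly hypometric), truncated to a
  physical range.
* **Noise**: additive white Gaussian position noise, SD 0.15° per sample
  per axis. Real tracker noise is temporally correlated (the hardware
  filters internally); white noise at equal RMS is the *harsher* spectrum
  for a velocity-based classifier, so passing recovery tests under it is
  conservative in that one respect — but no test here says anything about
  correlated drift, slippage or pupil-size artifacts, which the simulator
  does not model.
* **Blinks**: Poisson 12/min, uniform 100–300 ms durations, realized as
  both-eyes-invalid runs. **Data loss**: independent per-eye Bernoulli
  (0.002/sample), which exercises the left-only/right-only averaging
  branches; the two simulated eyes sit 0.3° apart so averaging is
  nontrivial.
* Gaze position chains across trials: each trial begins with a recentring
  saccade from the previous target back to the centre (uniform 150–400 ms
  latency after central-dot onset). These return saccades are part of the
  ground-truth saccade list, so detected-versus-true counts are
  comparable.

Sessions are reproducible: the schedule derives from the session seed and
each trial draws from its own substream, so truths do not shift when the
trial count changes.

The cohort generator adds a clinical table (age, sex, Hoehn & Yahr stage,
disease duration, MMSE, CANTAB PRM/SWM with configurable missingness —
42/62 MMSE and 22/62 CANTAB by default, nested) and links covariates to
per-subject oculomotor means through linear slopes (all zero by default,
which makes covariates and metrics exchangeable — the null cohort used
for type-I calibration). By default it emits subject-level aggregated
metrics directly from that model; this is what the statistical
calibration consumes, since hundreds of replicate cohorts of full
62-subject sessions would be prohibitive and would test the event
detector, not the statistics. `full_sessions = TRUE` additionally
simulates complete recordings per subject for end-to-end runs.

## Statistics

Spearman's ρ uses average ranks for ties. For n ≤ 10 complete pairs the
two-sided p-value is the exact permutation probability: for untied data
the permutation distribution of ρ depends only on n, so it is enumerated
once per n and cached; with ties the enumeration is conditional on the
observed rank multisets. Beyond n = 10 the usual
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation is used (the test suite
checks it against the exact distribution at n = 10). Pearson's r carries
the standard t-test. Degenerate inputs (fewer than 3 complete pairs, zero
variance) yield flagged results rather than numbers.

The correlation grid evaluates every metric × covariate pair on
pairwise-complete observations — subjects missing a score drop out of
that covariate's pairs only, matching how partially scored cohorts are
analysed — and applies **no multiple-testing correction**; the report
prints the number of tests as an explicit caveat. Spearman is the default
(appropriate for the ordinal Hoehn & Yahr stage); Pearson is available
for interval-scaled pairs. Effect-size adjectives use |ρ| bands
0.1/0.3/0.5 (configurable, since usage in the literature is
inconsistent).

## Evaluation conditions and problem sizes

The recovery checks in the test suite and `scripts/acceptance.R` run the
horizontal protocol (40 trials, 10 per ±10°/±18° amplitude) over 20
seeded sessions with blinks, anticipatory saccades and data loss disabled:

* **saccade-count equality** is evaluated at zero noise — at finite white
  noise an isolated position spike (≥ ~0.5°) occasionally yields a
  saccade-fragment pair around the spike sample that merging cannot
  absorb, which is exactly how a velocity-threshold classifier without
  noise reduction behaves;
* **onset/offset timing** (±8 ms) and **parameter recovery** (mean
  relative error of latency/amplitude/peak velocity) are evaluated at the
  default 0.15° noise.
* statistical calibration uses 500 null replicates and 100 effect
  replicates of 60-subject analytic cohorts (latency–age slope 2 ms/yr,
  age SD 9 yr, residual SD 20 ms).

## Numerical choices and known limitations

* Threshold comparisons are uniformly inclusive; timestamps are ms
  decimals; intervals half-open.
* An I-VT saccade onset is the *first supra-threshold sample*, which lags
  true motion onset by the threshold-crossing time of the velocity
  profile ($\approx (D/2\pi)\arccos(1 - 60/V_p)$, ~4 ms for a 9° saccade)
  plus up to one sample of grid quantization. Consequently measured
  latencies carry a small positive bias, and a simulated anticipatory
  saccade drawn within a few ms below the 100 ms cutoff can measure at or
  past it and pass the filter. This is a property of velocity-threshold
  detection itself (the clinical platform shares it), not of the
  simulator; the tests assert complete rejection for latencies ≤ 90 ms
  and that any accepted trial has measured latency ≥ 100 ms.
* Peak velocity from the 16 ms windowed estimator is a smoothed maximum
  and sits below the instantaneous peak (more so for short, small
  saccades); amplitude loses the sub-threshold tails of the profile.
  Both effects are inherent to the filter settings and stay within the
  recovery budgets above.
* Fixation merging absorbing saccade fragments means an isolated genuine
  miniature saccade (< 0.5° between stable fixations) would be erased;
  microsaccade and square-wave-jerk analysis is explicitly out of scope.
* The simulator does not model smooth pursuit, head slippage, pupil
  artifacts, correlated drift, or direction errors of anticipatory
  saccades; passing recovery tests shows the pipeline is correct under
  the stated models, not that it is robust to everything real data does.
* No control group and no multiple-testing correction are modelled,
  mirroring the analysis style the pipeline reproduces; the report's
  caveat line is deliberate.
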