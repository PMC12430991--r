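---
title: "Methods: rule-based VR stress detection and the calibrated simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based VR stress detection and the calibrated simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrstress)
```

## The detection model

`vrstress` treats stress detection as a fixed, auditable rule system over
two data streams sharing one session clock (seconds from session start):

* **Behavior** — controller motion (~90 Hz, tracker units) and a discrete
  event log (`prompt`, `action`, `success`, `failure` per task). Per trial,
  four binary indicators are computed and summed into the behavioral score
  `Sb` in 0–4.
* **Physiology** — an optional skin-conductance trace (μS), resampled to a
  uniform 5 Hz grid. A slope detector sets the binary physiological flag
  `Sp`.

Decision-level fusion is `Sf = alpha*Sb + beta*Sp` with defaults
`alpha = 1`, `beta = 1.5`, and stress is declared when `Sf >= 3`
(inclusive). The structure of this rule is easiest to see by enumeration
(and is frozen as a test): the stress set is exactly
`{Sb >= 3}` united with `{Sb = 2 and Sp = 1}` — strong behavioral evidence
alone suffices, while mild behavioral evidence needs physiological
confirmation.

The online wrapper is a three-tier logic evaluated once per GSR tick
(5 Hz, the slowest mandatory clock; once per trial close in behavior-only
mode):

1. **Immediate alert** when a single signal is overwhelming: smoothed
   conductance strictly above 0.7 μS, or dominant tremor frequency
   strictly above the configured bound (default 30 Hz).
2. **Selective fusion (gray zone)**: `S = 0.6*B + 0.4*Gnorm` with
   `B = Sb/4` and `Gnorm` the min–max normalized conductance; alert iff
   `S > 0.65` (strict). With GSR absent, `S = B`.
3. **No alert** otherwise; the system stays idle.

All comparison operators mirror their definitions exactly: the `Sf`
trigger is inclusive, every signal threshold is strict. Where source
descriptions disagree on strictness (a "greater than" in one place, "at
least" in another, for the 2 s hesitation and 3 s inactivity rules), the
strict form from the algorithm definition is adopted uniformly and every
threshold is exposed in configuration rather than hard-coded. One stated
tier-1 condition, "tremor RMS > 30 Hz", is dimensionally inconsistent (an
RMS is an amplitude, not a frequency); the only reading in hertz is a
dominant-frequency bound, so that is what `tier_decision()` implements,
with the threshold exposed as `tier1_tremor_freq`.

### Behavioral indicators: definitions and numerical choices

* **Hesitation**: delay from prompt to first action; trials with no action
  take the full trial duration as delay so hesitation is never undefined.
  Flag iff delay > 2 s.
* **Repeated errors**: flag iff the trial's failure count is ≥ 2.
* **Inactivity**: the longest sub-interval of the trial window containing
  no input event and no motion sample whose finite-difference speed
  exceeds `motion_eps` (1e-4 units/s). Flag iff that gap > 3 s.
* **Tremor**: no standard definition of the high-pass that isolates
  "jitter" exists, so a parameter-light choice is made: subtract, per
  axis, a centered moving average over 0.5 s — this passes the 4–12 Hz
  physiological tremor band essentially unattenuated while removing
  voluntary reach motion (< ~0.5 Hz) — then combine axes as a Euclidean
  magnitude and take its RMS over the window core. Flag iff RMS > 0.03
  tracker units. The dominant frequency is the zero-crossing rate of the
  first jitter axis halved: O(n), adequate for a single frequency-bound
  test, and checkable against a brute-force oracle. A constant trace
  yields exactly zero RMS (the constant case is short-circuited so
  floating-point accumulation cannot leak in).

Trial windows are half-open, `[prompt, next prompt or session end)`, which
assigns every event to exactly one trial; failure conservation across
trials is a property test.

### GSR conditioning

The filter is first-order exponential smoothing (`tau = 1 s`): causal
(hence streaming-compatible), one parameter, and with closed-form test
anchors (a constant is a fixed point; a unit step reaches `1 - 1/e` one
time constant after the edge). "Steep rise within 3 s" is read as an
ordinary-least-squares slope over the trailing 3 s window (15 samples at
5 Hz), evaluated every tick — more robust to single-sample noise than a
two-point difference, and equal to the closed-form least-squares oracle to
1e-9 in tests. The slope (and hence `Sp`) is invariant to constant
offsets; the 0.7 μS level flag deliberately is not — both facts are
property-tested.

Two distinct physiological tests coexist by design: the *slope* flag `Sp`
feeds `Sf`, while the *level* test (0.7 μS) lives in tier 1. The sources
defining them never state that one substitutes for the other, so the
package keeps both, separately configurable, rather than guessing them
equivalent.

`Gnorm` is min–max normalization against a calibration range, clamped to
[0, 1]. When no explicit `normalization_context` is supplied, the detector
calibrates per user over the first 10 s of the smoothed trace; a
degenerate (flat) calibration segment is widened to a 0.05 μS span so
`Gnorm` stays defined. Baseline-relative feature changes use
`(value - baseline)/baseline`, with the baseline the mean over the
non-stress classes (Negative and Neutral).

### Streaming semantics

Every per-tick computation is strictly causal (trailing windows only, and
the resampling grid is anchored at the first raw sample), so feeding a
session through `stream_step()` in any chunking — including sample by
sample — reproduces the batch `detect_session()` output exactly. This is
tested, not assumed, over randomized sessions. Work per tick is bounded by
the fixed trailing windows.

### The three-class rule classifier

`classify3()` is a scaled nearest-centroid rule: the minimal interpretable
classifier consistent with per-class feature medians. Default centroids
are the class medians of (hesitation s, tremble units, GSR μS) —
Negative (0.99, 0.0060, 0.62), Neutral (1.69, 0.0160, 0.77),
Positive (0.91, 0.0050, 0.61) — and each feature is scaled by the span of
the class medians so all three contribute comparably. Exact distance ties
resolve to Neutral (the contract is tested with constructed equidistant
points). The per-class continuous score used for one-vs-rest ROC ranking
is the negative scaled distance to that class's centroid; a threshold rule
system emits no other graded quantity.

Note the Negative and Positive centroids differ by far less than one
within-class standard deviation on every feature, while Neutral stands
apart on all three. Any classifier over these three features therefore
separates Neutral nearly perfectly and confuses Negative with Positive
often; the package's accuracy claim for the rule is only that it beats the
1/3 chance level decisively (a one-sided binomial test at p < 0.01 in the
acceptance suite).

## The simulator: what it emulates and how it was calibrated

No public dataset exists for this session design, so the simulator is the
package's test bed. It emulates, per stress class
(Negative / Neutral / Positive):

* class-conditional distributions of hesitation time, tremble amplitude
  and per-trial GSR level, anchored at the class medians above;
* strong GSR–behavior coupling: pooled Pearson correlations of GSR with
  hesitation (target 0.94) and with tremble amplitude (target 0.92);
* event-related skin conductance responses whose onset follows each
  stressor by 1–3 s;
* full multi-rate sessions: 90 Hz motion with voluntary reach plus
  band-limited (4–12 Hz) tremor whose RMS equals the sampled tremble
  feature, an event log realizing the sampled hesitation/failure behavior,
  a 5 Hz GSR trace, and the per-condition stressor schedule (baseline,
  red light, time pressure, and the combined high-stress battery).

### Marginals: why medians are anchored and means are not

The marginal family is a normal left-truncated at 0 (features are
nonnegative). `fit_location_scale()` solves the two closed-form moment
equations for (location, scale) when given a feasible (median, mean) pair.
Feasibility is a real constraint: a left-truncated normal is always
right-skewed, so its mean strictly exceeds its median; target pairs with
mean ≤ median admit no solution and are rejected. The calibration's
Neutral-class mean/median pairs differ by one unit in the last printed
digit in the *wrong* direction for two of three features (1.68 vs 1.69 s;
0.76 vs 0.77 μS) — gaps at display precision, not resolvable structure.
The third (tremble, 0.0170 vs 0.0160) is feasible but only with a scale
near 80% of the median, which would destroy both the concentration of the
sample median and the correlation calibration; the fit's documented scale
bound (35% of the median) excludes it. The default calibration therefore
anchors every class×feature at its **median** with a symmetric-regime
truncated normal (location = median, scale = cv × median), and accepts
that the generator's means equal its medians — within 0.6% of the stated
means where those exist, except tremble at 5.9%. The acceptance suite
asserts median recovery against the calibration targets and mean recovery
against the generator's own analytic means.

### Coupling: one latent arousal factor

Each trial draws a latent arousal `a ~ N(0,1)`; feature `j` gets the
Gaussian score `z_j = c_j a + sqrt(1 - c_j^2) e_j` and is mapped through
its class marginal's quantile function (a one-factor Gaussian copula).
Marginals are exact by construction; rank coupling is governed by the
loadings `c_j`, with the comonotone (`c = 1`) and independent (`c = 0`)
limits property-tested.

The pooled correlations mix two sources: the within-class copula channel
and the between-class alignment of the medians (Neutral is highest on all
three features). Writing each feature as between-class location plus
within-class spread gives a closed-form expression for the pooled r in
terms of the per-feature within-class coefficients of variation (CV) and
the loadings. Two facts drove the defaults:

* the GSR within-class CV must be small (≈ 0.08): its class medians
  (0.61–0.77 μS) overlap so much that with larger spread no loading ≤ 1
  can reach a pooled r of 0.94;
* with CVs fixed at (hesitation 0.18, tremble 0.20, GSR 0.08), the
  required within-class latent correlations are ≈ 0.835 (GSR–hesitation)
  and ≈ 0.843 (GSR–tremble), factored as loadings
  `c = (0.8787, 0.8868, 0.95)` with GSR as the strongest arousal proxy.

These values were derived analytically and confirmed by brute-force
simulation at 200,000 trials per class (pooled r = 0.9411 and 0.9208)
before being frozen as `sim_config()` defaults. The small CVs also keep
the class sample medians tightly concentrated: at 200 trials per class the
sample-median standard error is ≈ 1–2% of each target, comfortably inside
the ±5% recovery tolerance.

### Event-related responses

Each stressor spawns one SCR: onset latency uniform in
`[1, 3 - rise duration]` seconds after stressor onset (so both the onset
*and* the response peak fall within the 1–3 s window), a linear rise of
1.5 s at a slope drawn from U[0.15, 0.30] μS/s, then exponential decay
with a 4 s time constant. The 0.15 μS/s floor is deliberate: after the
1 s smoother and the 3 s OLS window, a 0.10 μS/s ramp measures only
≈ 0.043 μS/s — below the 0.05 detection threshold — while at 0.15 the
minimum measured slope across noise realizations is ≈ 0.065. With the
default measurement noise (sd 0.012 μS) the largest spurious baseline
slope observed across hundreds of simulated baseline sessions is
≈ 0.011 μS/s, a factor ~4.5 below threshold, so the detector fires on
every synthetic response and never on the baseline scenario — both are
acceptance checks. The ground-truth SCR schedule travels with each
synthetic session as an attribute so these checks need no inference.

### Scenario-to-class mapping and other conventions

Conditions and classes are distinct axes (a condition is a stressor
configuration; a class is a statistical profile), and no mapping between
them is given anywhere; the generator's convention is
Negative → baseline, Positive → red light, Neutral → the combined
high-stress battery, on the grounds that Neutral exhibits the strongest
responses of the three profiles. Why the class *named* Neutral shows the
strongest indicators is not something the calibration explains; the
simulator copies the statistics without imposing a valence interpretation,
and the labels are treated as opaque categories throughout. Tremble
features are RMS amplitudes; the synthetic tremor sinusoid's peak
amplitude is the feature × √2 so the extracted RMS matches the sampled
value. Default dataset size is 50 trials per class (150 total), consistent
with the order of magnitude implied by the calibration's correlation
p-values (~1e-60 at r ≈ 0.9 needs n in the low hundreds).

### What the simulator does *not* model

Real controller telemetry has artifacts the generator omits: tracking
dropouts, voluntary high-acceleration motion that can leak through the
0.5 s high-pass, posture shifts, and non-stationary tonic GSR drift,
electrode detachment, or temperature/humidity effects. Phasic/tonic EDA
decomposition is out of scope — smoothing is the only artifact handling.
Passing tests therefore demonstrate that the *rule system and its
calibration behave as specified under the stated statistical structure*,
not that the thresholds transfer to human data.

## Wearable adapter

`load_recording()` consumes a long-format CSV export (t, channel, value,
label) rather than any native serialized container, keeping the library
free of dataset-specific deserialization; samples labeled outside
{1 = baseline, 2 = stress} are dropped. Heart rate is estimated from the
blood volume pulse by peak detection (minimum inter-beat interval 0.33 s,
amplitude floor at mean + 0.25 sd), inverted inter-beat intervals gated to
20–250 bpm, interpolated to 4 Hz. Classification is a z-score threshold
against a baseline-segment calibration: stress iff the score exceeds `k`
baseline standard deviations (default `k = 1`, exposed in configuration —
no principled split or selection rule for `k` exists, so it is a
parameter, not a claim). Heart rate, when enabled, joins with the same
0.6/0.4 weighting as tier-2 fusion; the default is EDA-only, since EDA
carries the clearer stress signal and HR is the noisier, complementary
channel.

## Problem sizes and runtime choices

Test and acceptance runs use sizes chosen to make Monte-Carlo tolerances
meaningful while keeping the suite quick to iterate: median recovery at
200 trials per class, correlation recovery at the default 150-trial
dataset, SCR timing over several 4-trial sessions, online/offline
equivalence over twenty 3-trial sessions streamed in chunks, and the
AUC-versus-rank-statistic identity over 100 random fixtures at 1e-12. The
full suite runs in about half a minute; `scripts/acceptance.R` in a few
seconds.

## Known limitations

* Thresholds are global, not per user; the normalization context supports
  per-user calibration but no adaptive baselining is implemented.
* The Negative/Positive confusion of the three-class rule is intrinsic to
  its feature geometry (see above); reported AUCs for those classes hover
  near 0.75 on synthetic data.
* The tier-1 tremor-frequency bound (30 Hz) lies above the physiological
  tremor band (4–12 Hz) that the simulator generates, so that branch fires
  only on pathological input; it is kept because the rule system defines
  it, and it is configurable.
* Behavior-only mode scores trials at their close, so its alerts lag the
  5 Hz fused mode by up to one trial.
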