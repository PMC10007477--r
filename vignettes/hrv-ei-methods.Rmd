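---
title: "Methods: from ECG to emotional-intelligence markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ECG to emotional-intelligence markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(hrvei)
```

## The problem

Questionnaire-based emotional-intelligence (EI) assessment is vulnerable to
response distortion: people can answer the way they want to appear. Heart
rate variability (HRV) offers an involuntary complement — vagally mediated
beat-to-beat variation indexes emotion regulation, and how HRV *moves* over
a session (its dynamics) indexes regulation over time. This package
implements the full analysis chain needed to test that idea: score
participants' emotion recognition on an objective task, extract HRV and its
dynamics from ECG recorded while they watch emotion-eliciting stimuli, and
ask which physiological features statistically separate low from high
scorers — and at which score cut the separation is strongest.

Because no participant-level recordings are available to ship, every stage
is paired with a synthetic-data generator whose ground truth is known by
construction. The generators are first-class, tested code: they define the
study conditions under which the pipeline's claims are verified.

## Signal chain

### ECG to RR intervals

`detect_r_peaks()` is a Pan-Tompkins-style detector: band-pass 5–15 Hz
(3rd-order Butterworth, applied forward-backward so it is zero-phase),
differentiate, square, 150-ms moving average, then adaptive signal/noise
thresholds (`SPKI`/`NPKI` running estimates, threshold
`NPKI + 0.25 (SPKI − NPKI)`) over the local maxima of the detection
function, with a 200-ms refractory period. Each detection is refined to the
raw-signal argmax within ±75 ms, so reported beat times sit on the R wave
rather than on the (delayed) detection function. The record is zero-padded
by 0.5 s at both ends before filtering; without the padding a beat at the
very first sample has no left flank in the detection function and is
systematically missed.

`clean_rr()` flags intervals outside 300–2000 ms, or deviating more than
25% from the median of their five nearest in-bounds neighbours. The source
protocol states no artifact handling at all, so these are explicit,
conservative defaults, recorded in the output's `cleaning` attribute and
fully configurable. Flags are recomputed from interval values alone, which
makes cleaning idempotent. Rejected intervals are excluded from statistics
but never deleted — the beat-time axis stays intact. More than 20% rejected
intervals raises an epoch-quality error rather than silently producing
fragile spectra.

Epochs are half-open `[start, end)` and an interval belongs to the epoch
containing its *later* beat; a beat exactly on a boundary therefore opens
the later epoch. This is an arbitrary but unambiguous convention that makes
`segment_epochs()` a partition of the retained intervals.

### The 21-index set

Per window or epoch, `hrv_indices()` assembles:

* **Time domain** — BPM (`60000/mean(RR)`), SDNN (sample SD), RMSSD (root
  mean square of successive differences), pNN50 (percentage of successive
  differences strictly greater than 50 ms; a difference of exactly 50 ms
  does not count, and the comparison uses a 1-ns guard so intervals
  reconstructed from beat times do not flip the strict inequality through
  floating-point noise).
* **RSA** — respiratory sinus arrhythmia by the peak–valley method: the
  resampled tachogram is band-passed to 0.12–0.40 Hz, cycles are delimited
  by zero crossings, and RSA is the mean peak-to-trough excursion in ms.
  No formula is fixed by convention for a table position of RSA among
  time-domain indices; the peak–valley definition was chosen because it is
  a time-domain quantity and stays distinct from HF power (which the index
  set already contains as `HF`/`lnHF`). With no respiration channel the
  band is fixed a priori. A band variance below 1e-6 ms² returns 0 by
  convention (a constant tachogram has no cycles to average).
* **Frequency domain** — the tachogram (interval vs time of its later
  beat) is cubic-spline resampled at 4 Hz and a Welch estimate is formed:
  120-s segments, 50% overlap, per-segment linear detrend, Hann taper,
  one-sided density scaled so the integral over frequency reproduces the
  tachogram variance (verified to ±10% in tests). Band powers are
  trapezoidal integrals with interpolated band edges. Defaults: VLF
  0.0033–0.04, LF 0.04–0.15, HF 0.15–0.40 Hz. Index tables in this
  literature sometimes print LF from 0.004 Hz and HF from 0.015 Hz; those
  bands overlap each other and VLF, so the package treats them as
  typographic variants of the standard bands — the literal overlapping set
  remains available via `spectral_config(printed_bands = TRUE)`.
  Relative powers are normalized by the three-band sum, making
  `VLFp + LFp + HFp ≡ 1` an exact invariant (normalizing by total power
  would leave the sum dependent on out-of-band leakage). `tPow` integrates
  the full 0.0033–0.4 Hz band; `tHz` is reported as an equal duplicate
  because the conventional 21-index table carries both names with the same
  definition — consumers should treat them as one quantity. The dominant
  peak gives `dHz`; `dPow` integrates the density within ±0.015 Hz of it
  (a single-bin "peak power" would make the coherence ratio depend on
  frequency resolution), and `CohRatio = dPow / (tPow − dPow)`.

Logs are only defined for strictly positive band powers; a zero band power
raises an error rather than propagating `-Inf` into downstream t-tests.

### Sliding windows

`sliding_hrv()` advances a 180-s window in 10-s steps; windows lie entirely
inside the epoch, so a 360-s epoch yields exactly
`floor((360 − 180)/10) + 1 = 19` windows. The 180-s window is the shortest
length that still holds a whole 120-s Welch segment and resolves the lower
LF edge; the 10-s step is a package default (the protocol fixes the window,
not the step). A window whose computation fails contributes an `NA` row
instead of aborting the series.

## Dynamics and participant features

The affect-dynamics triad summarises each index's window series:
`variability` (sample variance, n−1 denominator), `instability` (mean
squared successive difference, MSSD — `NA`s break the successive-pair
chain), and `inertia` (lag-1 Pearson autocorrelation, undefined for
constant series). `instability` equals `RMSSD²` exactly on identical input,
which the tests exploit as a cross-module identity, and white noise has
expected instability twice its variability.

`participant_features()` turns the per-epoch window series into one record:

* the **HRV change score** per index is the stimulus-window mean minus the
  baseline-window mean (difference normalization; a ratio mode exists but
  is undefined for zero baselines);
* the **dynamics** are computed on the baseline-normalized window series
  spanning the whole session (baseline, stimulus, trailing neutral
  concatenated in time). The protocol does not state which series its
  dynamics used; computing them on the normalized per-window series is
  this package's choice, made because the sliding window and the baseline
  normalization are introduced together as preconditions of the dynamics.
* features are averaged across the four emotional-domain sessions into one
  record per participant (per-session output via
  `average_sessions = FALSE`). Pooling versus averaging is likewise not
  fixed by the protocol; averaging weights each domain equally regardless
  of minor differences in usable windows.

## Scoring

Items score 10 or 0, all-or-nothing. Photo (self-awareness) items require
the arousal rating's half, the valence rating's half, and the chosen
keyword all to match the target quadrant: on the 7-point scales, 5–7 counts
as high, 1–3 as low, and the midpoint 4 belongs to no quadrant (configurable
via `likert_half()`'s `midpoint`). Avatar (others-awareness) items require
the expression to be recognized *and* the chosen domain to match;
discrimination items require all placements correct. The full design — 3
evaluations × 4 domains × 10 stimuli × 10 points — totals 1200.
Stimulus-selection helpers use inclusive thresholds (an exact 81% photo is
kept) and peak-intensity ties resolve to the lower intensity.

## The cut-point sweep

`sweep_splits()` sorts participants by evaluation score and places
candidate cuts only between distinct score values (tied scores are never
split), with both groups at least `min_group = 5`. At each cut every
feature is tested with Welch's unequal-variance t-test (Satterthwaite df,
two-sided; pooled-variance optional) — Welch is the default because
observed group SDs of HRV features differ severalfold. No multiple-testing
correction is applied by default, matching the procedure the package
reproduces; Benjamini–Hochberg is available behind `adjust = "BH"`.

The best split maximizes the count of features with `p < 0.05` (strict).
Ties cascade: count at the next tier (`p < 0.01`), then the most balanced
split, then the lowest cut score. The reported `cut_score` is the lowest
score of the high group. `marker_table()` stars features `*` for
`p < 0.05` and `**` for `p < 0.01` (strict at both boundaries) and groups
them by source (plain HRV change score vs each dynamics expansion).

### What the sweep can and cannot recover

Because the maximizing cut is chosen after seeing all the tests, the
best-split count on pure-noise cohorts is stochastically larger than the
count at any fixed split — the selection effect the synthetic null
baseline exists to expose (`analysis/05_ei_sweep.R` prints a matched null
sweep for exactly this reason). The package's tests verify the two
calibrations that are achievable at the design size (22 low / 26 high, 21
features): a *fixed* split's mean significant count on null cohorts sits at
the binomial level `0.05 × 21 ≈ 1.05`, and with five features injected at
`d = 1.5` at least four of the five appear in the marker table in ≥ 95% of
seeds.

Recovering the *exact* generating cut is a different matter. At `d = 1.5`
the per-feature power of the Welch test is ≈ 0.99 at the true 22/26 cut —
but moving a few participants across the cut dilutes the effect only
slightly, so power stays near 1 across a broad range of neighbouring cuts.
The significant-count curve is therefore flat-topped over the middle of the
score range, and which cut attains the maximum is decided by the
false-positive noise of the 16 null features: in simulation the true cut is
in the argmax set only ~17% of the time, so no tie-break rule can push
exact-cut recovery near 95%. The corresponding acceptance test asserts the
strict criterion and is expected to fail; it is retained deliberately as an
honest record that the count-maximizing estimator localizes a *region* of
good cuts, not the cut itself, at this effect size and sample size. In
practice the sweep curve (the Fig.-9-style output) should be read as an
interval estimate, and the marker table at the best split — which is stable
across that interval — as the substantive result.

`check_normality()` (Shapiro–Wilk plus Q-Q coordinates) supports the
score-distribution check that precedes the sweep.

## Synthetic generators

`generate_rr_series()` builds intervals sequentially:
`RR(t) = mean_rr + Σ A_k sin(2π f_k t + φ_k) + N(0, noise_sd)`, with beat
times the cumulative sums. Additive sinusoidal modulation of the interval
sequence was chosen over an integral-pulse-frequency model because it
places spectral power at known frequencies analytically — testability over
physiological fidelity. Draws below 1 ms are redrawn up to 10 times and
then rejected as degenerate (sub-millisecond intervals are meaningless, and
a hard floor also prevents beat times stalling asymptotically when the
deterministic part decays through zero); an iteration cap backs this up.
Identical specs reproduce bit-identical series.

`synthesize_ecg()` places a unit Gaussian spike (~80 ms wide) at each beat
on a zero baseline. No P/T waves, no ectopy, no respiration signal: the
record exists so detection can be scored against known beats, and passing
the round trip (sensitivity and PPV ≥ 0.99 at ±10 ms; interval MAE below
twice the sample period) says the chain is self-consistent — not that the
detector is validated for clinical ECG morphology or noise.

`generate_cohort()` draws feature values `N(0, σ)` for the low group and
`N(dσ, σ)` for the high group, with 22/26 group sizes and the score cut at
820 of 1200 as defaults, scores on a 10-point grid strictly below / at or
above the cut. `generate_responses()` makes exactly
`round(n × accuracy)` items fully correct and the rest keyword-mismatched,
so requested accuracies are hit exactly.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 360-s epochs for spectral
checks (451 beats at 800 ms), 120-s records × 10 seeds for the detection
round trip, 100 cohorts of 48 × 21 for marker recovery, and 500 null
cohorts for calibration — sizes at which every Monte-Carlo band in the
tests is comfortably wide relative to its standard error. Other constants:
spline interpolation is used for all tachogram resampling (cubic, as is
standard for RR series); filter transients are trimmed (10 s) before RSA
cycle extraction; Welch detrending is per-segment linear; the degenerate
two-constant-group t-test returns `p = 1` for equal means by convention.

## Limitations

* The synthetic generators emulate stationary oscillatory tachograms with
  Gaussian interval noise; real RR series carry nonstationarity, ectopy
  and respiration-coupled amplitude modulation that these tests do not
  probe.
* RSA without a respiration channel assumes respiration stays inside
  0.12–0.40 Hz.
* The sweep reports raw significance counts by design; any confirmatory
  use needs the null-sweep calibration or the BH option.
* Printed group statistics from the motivating literature are not
  reproduction targets here: the participant-level data behind them were
  never deposited, and their summary tables are not internally consistent
  enough to recompute from (see the package README).
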