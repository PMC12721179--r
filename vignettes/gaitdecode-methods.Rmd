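---
title: "Methods: from limb tracking and spikes to gait phase, tuning and population decoding"
author: "gaitdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from limb tracking and spikes to gait phase, tuning and population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, what the synthetic generator does
and does not emulate, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The analysis problem

A session couples three data streams: per-frame 2-D coordinates of six
tracked features (four limbs, nose, tail base; mm, 80 frames/s), spike
times of sorted single units (s), and unit metadata (region label from
M1/mPFC/DMS/DLS, optional layer or subregion tag). The pipeline turns
these into (i) behavioural events — walking bouts, strides, per-limb gait
phase; (ii) single-unit tuning statistics; (iii) population decoding
accuracies with chance controls. All parameters live in one flat
configuration (`defaultConfig()`), all randomness flows from one master
seed through a per-stage hash (`deriveSeed()`), so any stage re-run with
the same inputs is bitwise reproducible.

# Kinematics

**Smoothing.** Coordinates are smoothed with a third-order Savitzky–Golay
filter. The window length is not dictated by the problem, so we use 7
frames (87.5 ms): long enough to suppress frame-to-frame tracking noise,
short enough to pass 8 Hz limb oscillations essentially unattenuated. A
7-frame cubic fit reduces white-noise sd only by a factor ≈ 0.75; noise
suppression is therefore shared between this filter and the later gait
band-pass, rather than bought with a long window that would distort fast
swings.

**Body speed and bouts.** Per-limb speed is the frame-difference
displacement × 80; body speed is the RMS over the four limbs. Candidate
bouts are episodes with body speed ≥ 50 mm/s sustained ≥ 0.5 s (the
threshold equals the lowest analysed speed bin; the sustain requirement
removes twitches). Each candidate onset is refined to the body
acceleration peak — centred difference of body speed — within a 50-frame
window, and discarded unless that peak's topographic prominence exceeds
1000 mm/s². Bout offsets are not part of the published rule; we end a
bout when speed stays below 50 mm/s for 0.25 s, which bounds the stride
search without clipping brief within-bout decelerations. Bouts shorter
than 1 s are dropped; when two bouts come closer than 1 s we keep the
earlier one (the rule only fixes that one of the pair must go; keeping
the earlier preserves the onset that triggered the pair).

**Strides and phase.** Limb positions are projected onto the nose→tail
axis, so small values mean "limb close to the nose". The projection is
de-meaned and band-passed 0.5–8 Hz with a second-order Butterworth filter
run forward and backward (zero phase; de-meaning tames edge transients).
Stance onsets are the minima of this signal, swing onsets the maxima;
alternation is enforced by keeping the more extreme of any two
consecutive same-type extrema, and partial cycles at bout edges are
dropped. Gait phase is the angle of the FFT-based analytic signal,
shifted by +180° so that minima — stance onsets — sit at 0°, wrapped to
[0°, 360°). The phase origin is a convention; every downstream statistic
is rotation-equivariant, so only consistency matters.

# Single-unit statistics

**Peri-event rates.** Spike counts in 25 ms bins are convolved with a
Gaussian kernel (σ = 0.1 s) and block-averaged into 0.1 s bins for the
modulation analysis (±1 s window) or 0.2 s bins for decoding (±1.5 s).
Counting is padded four kernel σ beyond the window so kernel mass is
conserved at the edges: a single spike contributes exactly one spike of
integrated rate.

**Onset modulation.** Each 0.1 s bin is compared against the −1 to −0.9 s
baseline bin with a two-sided paired t-test across trials; a unit is
modulated in a bin when p < 0.05, uncorrected. The absence of a
multiple-comparison correction is deliberate — the statistic of interest
is the *fraction* of significant units per bin, whose null level (5%) is
itself verified by simulation in the acceptance suite. Zero-variance
differences (e.g. the baseline tested against itself) are assigned p = 1.

**Speed tuning.** Walking frames are binned by body speed in 20 mm/s
steps from 50 to 310 mm/s (13 bins). A unit's rate per bin is its spike
count over the bin's occupancy time; unoccupied bins are dropped, and
units whose speed exposure covers fewer than three bins are excluded
rather than given a meaningless correlation. R² is the squared Pearson
correlation between rate and bin-centre speed, with the two-sided
p-value from the correlation test.

**Phase locking.** Spikes are assigned the phase of their containing
video frame (12.5 ms; sub-frame interpolation would pretend to more
temporal precision than the 80 Hz tracking supports). Rates in 24 × 15°
bins are normalised by per-bin occupancy time before the circular
resultant is taken — without occupancy correction, any covariation of
speed with phase sampling would masquerade as phase tuning. The "r"
statistic is the modulus of the occupancy-normalised, rate-weighted
resultant; its argument is the preferred phase. The jitter null
displaces each spike independently by U(−0.15, +0.15) s. The published
wording would also admit a whole-train shift; per-spike jitter is the
stricter null — it destroys within-cycle structure completely while
preserving slow rate fluctuations — and is kept configurable in spirit by
being isolated in one function. Jittered spikes that land outside
walking frames drop out of that surrogate, exactly as real spikes outside
bouts never enter the statistic. A unit is phase locked when its r
exceeds the 95th percentile of 1000 surrogates for at least one limb.

# Population decoding

**Trial construction.** The time task takes each bout's ±1.5 s window as
one trial with 15 population vectors (0.2 s classes). The speed task
labels non-overlapping, fully-walking 0.2 s bins with one of four 50 mm/s
classes (50–250 mm/s) and balances classes exactly by construction. The
phase task treats one stride as one trial, averaging the smoothed 25 ms
rates over the frames belonging to each of twelve 30° bins; strides that
do not visit all 12 bins are skipped. The published description of the
phase decoder also mentions 0.2 s averaging, which cannot apply within a
~0.4 s stride holding 12 classes; the per-stride phase-bin averaging is
the reading consistent with "one trial equals one stride" and is what we
implement. Sessions are pooled into a pseudo-population by concatenating
unit axes at matching trial index after per-session random selection of
the quota (50 bout trials, 100 per speed class, 200 strides at full
scale); sessions below quota are dropped, not resampled, to avoid
duplicated trials.

**Classifier.** One radial-basis binary SVM per unordered class pair
(105 models for 15 classes), majority vote across models. Features are
standardised per unit with training-set statistics — radial kernels on
raw rates would let high-rate units dominate the metric. The kernel
bandwidth defaults to the median heuristic on the standardised training
set; cost defaults to 10. The full 5-fold cross-validated grid search
(cost ∈ {0.1, 1, 10, 100} × bandwidth scale ∈ {0.1, 0.3, 1, 3, 10},
enumerated in fixed order, capped at 20 evaluations) is implemented and
switchable via `svm_tune`, but is off by default: at the reduced problem
sizes this package targets, the median-heuristic/cost-10 operating point
is already in the flat region of the tuning surface, and the search
multiplies runtime by two orders of magnitude. Vote ties are broken by
the largest summed signed decision-function margin over the tied
classes, then by lowest class index — a deterministic rule, so identical
seeds give identical predictions.

**Evaluation.** An outer loop draws `n_draws` random unit subsets of
size N; an inner loop holds out random trials (1 for time, 2 for speed,
4 for phase), trains on the rest and classifies the held-out vectors.
Confusion matrices are row-normalised; overall accuracy is the mean of
per-class accuracies (balanced by construction). Errors are RMSE over
physical bin centres (s or mm/s; a bin-count RMSE is also reported) or,
for phase, the mean absolute angular difference wrapped to [0°, 180°].
Chance bands come from re-evaluating tensors in which each trial's class
axis is permuted; the per-class 2.5/97.5 percentiles over shuffles form
the band. Pre-start and post-start summaries average the three class
bins whose centres fall in −0.9…−0.3 s and +0.3…+0.9 s.

# Group comparisons

Cross-region contrasts operate on draw-level accuracy distributions
(with the explicit caveat, logged into every report, that draws share
units and trials and are not independent samples). Each group is gated
through a Lilliefors normality test at p < 0.05 — the gate threshold is
not published; 0.05 is the conventional choice — sending the comparison
to one-way ANOVA + Tukey or Kruskal–Wallis + Dunn–Šidák (independent),
or repeated-measures ANOVA vs Friedman with Šidák-corrected pairwise
tests (paired, e.g. per-limb vector lengths). Proportions (percent
locked, percent speed-correlated) are compared by pairwise chi-squared
tests Šidák-adjusted for the 6 pairwise comparisons among four regions.
Omnibus tests are standard library routines; only Dunn's rank z
statistic is computed in-package (no implementation ships with base R).

# The synthetic generator

The generator exists to make every stage falsifiable, not to be a
biomechanical model. It emulates:

* **Bout structure** — alternating rests and walking bouts (means 2.5 s
  and 3 s, jittered), each bout opening with a 2-frame commanded-speed
  transient that guarantees an acceleration peak well above the
  1000 mm/s² prominence gate, then relaxing with AR(1) noise toward a
  per-bout cruise speed drawn from the full 50–310 mm/s range (so all
  four decoding speed classes are populated).
* **Trot kinematics** — a common phase oscillator at 2.5 Hz (diagonal
  limb pairs in phase, the two diagonals 180° apart), per-frame phase
  jitter (sd 3°), sub-linear coupling of stride frequency to body speed
  (factor 0.6 + 0.4·v/v̄ — at 80 frames/s a fully proportional coupling
  would make fast strides too short to sample all twelve 30° bins), an
  asymmetric stride waveform cos(φ − 0.4 sin φ) giving a faster swing
  than stance with stance onset (full protraction) at φ = 0, and stride
  amplitude growing with speed (slow gait takes shorter steps).
* **Tracking noise** — AR(1)-correlated positional noise with marginal
  sd 0.5 mm (≈ the tracking error of 0.3 mm/pixel video). Correlation
  matters: white noise of this amplitude differentiates into tens of
  mm/s of spurious limb speed, which real, temporally smeared tracking
  error does not produce.
* **Spike trains** — inhomogeneous Poisson by thinning of a
  piecewise-constant intensity on a 1 ms grid, so the realised intensity
  is exact. The log intensity is log b + s(t)·log(1 + A/b) + g·v(t) +
  κ·cos(θ(t) − θ₀): the log link guarantees positivity, the κ term in
  the exponent makes the phase tuning exactly von Mises (so the binned
  statistic can be checked against the I₁(κ)/I₀(κ) closed form), and
  the ramp is parameterised so its peak adds exactly A Hz over baseline.
  The ramp shape — linear rise over the lead time to a peak 0.1 s after
  onset, then exponential decay — is the simplest form matching
  preparatory activity that builds before onset and peaks just after.
  The speed gain g is log-linear (units: log-Hz per mm/s).

Two presets encode the canonical tuning families for contrast
experiments: "DMS-like" (large ramps, long ~0.8 s leads, weak phase
coupling κ ≈ 0.3) and "M1-like" (small ramps, strong coupling κ ≈ 2,
larger speed gain). These are calibration knobs chosen to produce
clearly detectable effects at desk scale; they are not estimates of any
recorded population's tuning-strength distribution, which is not
published.

**What the generator does not emulate** — and hence what passing tests
cannot certify about real data: 2-D limb trajectories (only the
along-body projection is structured), grooming and rearing (no
non-locomotor confounds for bout detection to reject), tracking dropouts
and identity swaps, non-Poisson spike history (refractoriness,
bursting), slow drift in excitability, and any dependence between units
beyond shared behavioural covariates. The end-to-end Hilbert phase
against generator truth carries ~18° of interior error plus larger
bout-edge transients; realised vector lengths are correspondingly
attenuated relative to their asymptotic von Mises values, which is the
expected behaviour of the phase estimator, not a defect — tests that
need the exact closed form use an ideal sawtooth phase series instead.

# Numerical choices and degenerate inputs

* Phase bins assign spikes by `floor(phase/width)`, with phase exactly
  360° folded into the last bin; empty-occupancy bins get zero weight.
* Units with no walking spikes, or speed exposure under three bins, are
  flagged and excluded rather than scored.
* A constant filtered signal has no phase and raises an error; a
  monotone signal yields zero strides.
* `quantile(type = 7)` defines the jitter threshold; with zero jitter
  every surrogate equals the observed r, so such units are never locked.
* Session tables are written deterministically (fixed column order,
  full-precision `fwrite`), so identical sessions produce byte-identical
  files and the whole pipeline under one seed is byte-identical,
  verified in the acceptance suite.

# Problem sizes

The defaults mirror the full-scale analysis (50 draws, 50 iterations,
200/100 units, 1000 jitter surrogates). The test and acceptance suites
run the same code at reduced scale, chosen once as the smallest sizes at
which every statistical property is still sharply testable: sessions of
100–600 s, cohorts of 6–110 units, 2–10 draws with 2–10 iterations,
50–500 surrogates, and per-session quotas of 8–80 trials. The regional
contrast experiment uses two 55-unit single-session cohorts of 300 s and
10 draws of 50 units, matching the draw/unit structure of the full
analysis at roughly a quarter of its unit count.

# Known limitations

* Bout acceptance has no behavioural veto: real analyses inspect
  candidate bouts for rhythmicity by eye, and the automated surrogate
  (strides must be segmentable) may admit movement a human would
  reject. On synthetic data this is moot — all bouts are genuine.
* The pseudo-population assumes independence of trials across sessions;
  this is an assumption of the method being reproduced, not a claim.
* Draw-level accuracy samples reuse units and trials; group tests on
  them overstate independence (flagged in every report).
* The phase decoder's accuracy depends on stride coverage of all 12
  bins; very fast gait at 80 frames/s thins the per-bin frame counts.
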