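# gaitdecode

Tools for analysing self-initiated locomotion from high-speed limb
tracking recorded together with single-unit spike trains — the data
produced by open-field recordings in which a bottom-up camera tracks the
four limbs, nose and tail base at 80 frames/s while silicon probes record
single units from motor cortex (M1), medial prefrontal cortex (mPFC) or
dorsal striatum (DMS/DLS).

The package answers three questions about such recordings:

1. **When does the animal walk, and where is each limb in its stride?**
   Walking bouts are detected from whole-body speed (the RMS of the four
   limb speeds) and aligned to the peak of body acceleration, requiring a
   peak prominence above 1000 mm/s² inside a 50-frame search window and a
   minimum bout duration of 1 s. Within bouts, each limb's position is
   projected onto the nose–tail axis, band-passed to the gait band
   (0.5–8 Hz), and segmented into strides: stance onsets at the signal
   minima (limb closest to the nose), swing onsets at the maxima. The
   instantaneous gait phase θ(t) ∈ [0°, 360°) is the angle of the
   analytic (Hilbert) signal, referenced so stance onset sits at 0°.

2. **How is each neuron tuned to locomotion?** Peri-onset firing rates
   (25 ms bins, Gaussian-smoothed with σ = 0.1 s) are tested bin-by-bin
   against a −1 to −0.9 s baseline with paired t-tests; speed tuning is
   the squared Pearson correlation R² between the mean rate in 20 mm/s
   speed bins (50–310 mm/s) and the bin-centre speed; spike–gait coupling
   is the mean vector length

   r = |Σₖ wₖ e^{iθₖ}| / Σₖ wₖ,  k = 1…24,

   the resultant of occupancy-normalised rates wₖ in 24 × 15° phase bins
   (r = 0 uniform, r = 1 perfectly locked), tested against a null built
   by jittering every spike within ±0.15 s (1000 surrogates, 95th
   percentile).

3. **What does the population know?** Time around walking onset (15 ×
   0.2 s classes spanning ±1.5 s), body-speed class (4 × 50 mm/s classes,
   50–250 mm/s) and gait-phase class (12 × 30° classes) are decoded from
   pseudo-population rate vectors with a one-against-one SVM ensemble:
   one radial-basis binary classifier per class pair (105 for the time
   task), prediction by majority vote, accuracy distributions over 50
   random draws of N units with held-out-trial evaluation, chance bands
   from within-trial label shuffles, and errors reported as RMSE
   (seconds, mm/s) or mean absolute angular error (degrees).

A synthetic-session generator (`generateKinematics()`,
`generateSpikes()`, `generateCohort()`) produces sessions with the same
statistical structure — trot-like kinematics with known bout onsets and
limb phases, and inhomogeneous-Poisson spike trains with known ramps,
speed gains and von Mises phase tuning — so every stage of the pipeline
can be validated against ground truth without any recorded data.

## Worked example

```r
library(gaitdecode)

ses <- generateKinematics(duration = 120, seed = 3)
ses@units <- list(
  generateSpikes(ses, tuningProfile(baseline_rate = 10), seed = 1,
                 unitId = "u1", region = "M1"),
  generateSpikes(ses, tuningProfile(baseline_rate = 6, phase_kappa = 2,
                                    preferred_phase = 90,
                                    preferred_limb = "LR"),
                 seed = 2, unitId = "u2", region = "M1"),
  generateSpikes(ses, tuningProfile(baseline_rate = 8, ramp_amplitude = 12),
                 seed = 3, unitId = "u3", region = "DMS"))
ses
#> GaitSession 'synthetic-3': 120.0 s at 80 fps, 9600 frames, 3 units
#>   ground truth: bouts, phase, speed

seg <- segmentSession(ses)
nrow(seg$bouts)    #> 21 walking bouts
nrow(seg$strides)  #> 613 strides across the four limbs
head(seg$bouts, 3)
#>   onset_frame offset_frame peak_prominence
#> 1         218          494        6321.992
#> 2         649          889        5855.571
#> 3        1094         1287        6748.774

tab <- unitStats(ses, seg, seed = 1, jitterIterations = 500)
tab[, c("unit_id", "region", "R2", "speed_p", "r_LR",
        "preferred_phase_LR", "locked_any")]
#>   unit_id region       R2 speed_p   r_LR preferred_phase_LR locked_any
#> 1      u1     M1 0.073042  0.3718 0.0390               21.0      FALSE
#> 2      u2     M1 0.378906  0.0251 0.6732               86.7       TRUE
#> 3      u3    DMS 0.000248  0.9592 0.0356              120.9      FALSE
```

The untuned Poisson unit (`u1`) and the ramp-only unit (`u3`) show small
vector lengths and fail the jitter test; the unit generated with von
Mises phase tuning (κ = 2, preferred phase 90° on the left-rear limb)
comes back with r = 0.67, a preferred phase of 86.7°, and a significant
jitter test — parameter recovery through the entire tracking → filtering
→ phase → statistics chain.

For population decoding, build a cohort and a trial tensor:

```r
cohort <- generateCohort(cohortSpec(
  regions = list(M1 = presetProfile("M1-like", 55)),
  duration = 300, seed = 101))
segs <- lapply(cohort, segmentSession)
tensor <- buildTrials(cohort, segs, "phase",
                      modifyList(defaultConfig(), list(quota_phase = 80)))
res <- evaluateDecoder(tensor, nUnits = 50, nDraws = 10, nIterations = 10)
res  # overall accuracy vs the 1/12 chance level, MAE in degrees
```

`runAll()` chains every stage over a multi-region cohort and writes
`report.json` plus per-stage tables; `compareGroups()` provides the
normality-gated ANOVA/Kruskal–Wallis comparisons (Tukey or Dunn–Šidák
post hoc) used for cross-region contrasts.

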