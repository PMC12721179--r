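# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 120 s kinematics-only session plus its segmentation
walkFixture <- function() fixture("walk120", function() {
  ses <- generateKinematics(duration = 120, seed = 3)
  list(session = ses, seg = segmentSession(ses), truth = groundTruth(ses))
})

# 600 s session with long walking exposure, for phase statistics
longWalkFixture <- function() fixture("walk600", function() {
  ses <- generateKinematics(gaitParams(bout_duration = 5, bout_gap = 2),
                            duration = 600, seed = 2)
  list(session = ses, seg = segmentSession(ses), truth = groundTruth(ses))
})

# Ideal sawtooth phase series: uniform phase advance, every frame walking.
# Used as a controlled input for circular-statistics oracles.
idealPhase <- function(durationS = 600, strideHz = 2.5, fps = 80) {
  wrapDeg((seq_len(durationS * fps) - 1) * 360 * strideHz / fps)
}

# Poisson spikes on a frame grid with rate exp(log(base) + kappa*cos(...)),
# by per-frame thinning; independent of the package's generator.
spikesFromPhase <- function(phaseDeg, kappa, prefDeg = 90, base = 10,
                            fps = 80, seed = 99) {
  set.seed(seed)
  lam <- base * exp(kappa * cos((phaseDeg - prefDeg) * pi / 180))
  counts <- stats::rpois(length(lam), lam / fps)
  frames <- rep(seq_along(lam), counts)
  sort((frames - 1 + stats::runif(length(frames))) / fps)
}

# Linearly separable trial tensor: class k has mean rate k on every unit,
# tight noise; any sane decoder reaches perfect accuracy.
separableTensor <- function(task = "time", nTrials = 8, nUnits = 6,
                            K = c(time = 15, speed = 4, phase = 12)[[task]],
                            seed = 42, sdNoise = 0.05) {
  set.seed(seed)
  arr <- array(0, c(nTrials, nUnits, K))
  for (k in seq_len(K))
    arr[, , k] <- matrix(5 * k + stats::rnorm(nTrials * nUnits, 0, sdNoise),
                         nTrials, nUnits)
  cv <- switch(task,
    time = seq(-1.5 + 0.1, 1.5 - 0.1, by = 0.2),
    speed = c(75, 125, 175, 225),
    phase = seq(15, 345, by = 30))
  new("TrialTensor", task = task, rates = arr, classValues = cv,
      unitIds = sprintf("u%02d", seq_len(nUnits)),
      sessionIds = rep("s1", nUnits))
}

# Zero-information tensor: iid rates, labels carry nothing.
nullTensor <- function(task = "time", nTrials = 10, nUnits = 8, seed = 7) {
  K <- c(time = 15, speed = 4, phase = 12)[[task]]
  set.seed(seed)
  arr <- array(stats::rexp(nTrials * nUnits * K, 1 / 8), c(nTrials, nUnits, K))
  cv <- switch(task,
    time = seq(-1.4, 1.4, by = 0.2),
    speed = c(75, 125, 175, 225),
    phase = seq(15, 345, by = 30))
  new("TrialTensor", task = task, rates = arr, classValues = cv,
      unitIds = sprintf("u%02d", seq_len(nUnits)),
      sessionIds = rep("s1", nUnits))
}

# Reduced-scale config for decoding tests
reducedConfig <- function() {
  cfg <- defaultConfig()
  cfg$quota_time <- 30; cfg$quota_speed <- 40; cfg$quota_phase <- 60
  cfg$n_draws <- 3; cfg$n_eval_iterations <- 5
  cfg$jitter_iterations <- 200
  cfg
}

# A small session with a few tuned units, for I/O and pipeline tests
miniSessionFixture <- function() fixture("mini", function() {
  ses <- generateKinematics(duration = 60, seed = 12)
  ses@units <- list(
    generateSpikes(ses, tuningProfile(baseline_rate = 10), seed = 1,
                   unitId = "m-u1", region = "M1"),
    generateSpikes(ses, tuningProfile(baseline_rate = 6, phase_kappa = 2),
                   seed = 2, unitId = "m-u2", region = "M1"),
    generateSpikes(ses, tuningProfile(baseline_rate = 8, ramp_amplitude = 10),
                   seed = 3, unitId = "m-u3", region = "DMS"))
  validObject(ses)
  ses
})
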