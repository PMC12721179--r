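test_that("trot geometry: diagonal limbs in phase, ipsilateral antiphase", {
  truth <- walkFixture()$truth
  ok <- !is.na(truth$phase$LF)
  dLFRR <- circMeanDeg(circDiffDeg(truth$phase$LF[ok], truth$phase$RR[ok]))
  dLFRF <- circMeanDeg(circDiffDeg(truth$phase$LF[ok], truth$phase$RF[ok]))
  expect_lt(min(abs(dLFRR), 360 - abs(dLFRR)), 5)
  expect_lt(abs(dLFRF - 180), 5)
})

test_that("generator is seed-deterministic and stride period matches", {
  a <- generateKinematics(duration = 40, seed = 9)
  b <- generateKinematics(duration = 40, seed = 9)
  expect_identical(kinematics(a), kinematics(b))
  expect_identical(groundTruth(a), groundTruth(b))
  c <- generateKinematics(duration = 40, seed = 10)
  expect_false(identical(kinematics(a), kinematics(c)))

  # 2.5 Hz at 80 fps: ground-truth stance onsets ~32 frames apart
  truth <- walkFixture()$truth
  ph <- truth$phase$LR
  wraps <- which(diff(ph) < -180)
  gaps <- diff(wraps)
  gaps <- gaps[gaps < 80]     # within-bout intervals only
  expect_equal(median(gaps), 32, tolerance = 0.05)
})

test_that("ground-truth phase restarts at stance reference each cycle", {
  truth <- walkFixture()$truth
  ph <- truth$phase$LF
  wraps <- which(diff(ph) < -180) + 1L
  expect_lt(median(abs(circDiffDeg(ph[wraps], 0))), 10)
})

test_that("spike counts follow the intensity integral", {
  ses <- fixture("spk100", function() generateKinematics(duration = 100, seed = 1))
  # baseline-only: expectation = rate * duration
  u <- generateSpikes(ses, tuningProfile(baseline_rate = 10), seed = 5)
  n <- length(spikeTimes(u))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))

  # with phase tuning: oracle expectation integrates exp(kappa cos) over
  # the ground-truth phase series at 1 ms resolution
  prof <- tuningProfile(baseline_rate = 6, phase_kappa = 1.5,
                        preferred_phase = 40, preferred_limb = "RF")
  u2 <- generateSpikes(ses, prof, seed = 6)
  gt <- groundTruth(ses)
  tGrid <- seq(0, duration(ses) - 1e-3, by = 1e-3)
  th <- gt$phase$RF[pmin(nrow(kinematics(ses)), floor(tGrid * 80) + 1L)]
  lam <- prof$baseline_rate *
    exp(ifelse(is.na(th), 0,
               prof$phase_kappa * cos((th - prof$preferred_phase) * pi / 180)))
  expected <- sum(lam) * 1e-3
  expect_lt(abs(length(spikeTimes(u2)) - expected) / sqrt(expected), 4)
})

test_that("unmodulated units have uniform spike-phase distributions", {
  lw <- longWalkFixture()
  u <- generateSpikes(lw$session, tuningProfile(baseline_rate = 12), seed = 4)
  pl <- phaseLocking(u, groundTruth(lw$session)$phase$LR)
  expect_lt(pl$r, 0.05)
})

test_that("phase-tuning parameters are recovered from generated spikes", {
  lw <- longWalkFixture()
  u <- generateSpikes(lw$session,
                      tuningProfile(baseline_rate = 12, phase_kappa = 2,
                                    preferred_phase = 90,
                                    preferred_limb = "LR"), seed = 7)
  # against ground-truth phase, recovery is tight
  pl <- phaseLocking(u, groundTruth(lw$session)$phase$LR)
  expect_lt(abs(circDiffDeg(pl$preferred_phase, 90)), 10)
  # and measured (Hilbert) phase preserves the preferred direction
  plm <- phaseLocking(u, lw$seg$phase$LR)
  expect_lt(abs(circDiffDeg(plm$preferred_phase, 90)), 15)
})

test_that("cohorts carry the requested units and tuning contrast", {
  spec <- cohortSpec(regions = list(
    M1 = regionProfile(12, phase_kappa = c(2, 0.3)),
    DMS = regionProfile(8, phase_kappa = c(0.3, 0.1))),
    duration = 120, seed = 21)
  cohort <- generateCohort(spec)
  regions <- unlist(lapply(cohort, function(s)
    vapply(units(s), region, character(1))))
  expect_equal(sum(regions == "M1"), 12)
  expect_equal(sum(regions == "DMS"), 8)
  for (s in cohort) {
    expect_true(validObject(s, test = TRUE))
    expect_true(is.data.frame(groundTruth(s)$profiles))
  }

  # realized vector length orders by the region's kappa
  rByRegion <- lapply(cohort, function(s) {
    seg <- segmentSession(s)
    vapply(units(s), function(u) phaseLocking(u, seg$phase$LR)$r, numeric(1))
  })
  m1r <- unlist(rByRegion[grep("^M1", names(rByRegion))])
  dmsr <- unlist(rByRegion[grep("^DMS", names(rByRegion))])
  expect_gt(mean(m1r, na.rm = TRUE), mean(dmsr, na.rm = TRUE))

  # seed change: different spikes, identical schema
  cohort2 <- generateCohort(modifyList(spec, list(seed = 22)))
  expect_identical(names(cohort2), names(cohort))
  expect_false(identical(spikeTimes(units(cohort[[1]])[[1]]),
                         spikeTimes(units(cohort2[[1]])[[1]])))
})

test_that("generator rejects infeasible requests", {
  expect_error(generateKinematics(duration = 3), "too short")
  expect_error(gaitParams(stride_frequency = 10), "0.5-8")
  expect_error(gaitParams(bout_duration = 0.5), ">= 1 s")
  expect_error(tuningProfile(phase_kappa = -1), "phase_kappa")
  expect_error(tuningProfile(baseline_rate = 0), "baseline_rate")
})
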