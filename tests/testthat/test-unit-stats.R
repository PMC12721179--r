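test_that("peri-event rates conserve spike mass and scale", {
  # no spikes at all
  rm0 <- estimateRates(numeric(0), c(5, 10), window = c(-1, 1))
  expect_true(all(rm0$rates == 0))
  expect_equal(dim(rm0$rates), c(2L, 20L))

  # one spike exactly at each event: smoothed rate integrates to 1 spike
  events <- c(10, 20, 30)
  rm1 <- estimateRates(events, events, window = c(-1, 1), outBin = 0.1)
  integ <- rowSums(rm1$rates) * rm1$width
  expect_true(all(abs(integ - 1) < 0.01))

  # homogeneous Poisson at 10 Hz over 200 trials: grand mean near 10 Hz
  set.seed(5)
  spikes <- sort(runif(10 * 500, 0, 500))
  ev <- seq(5, 495, length.out = 200)
  rm2 <- estimateRates(spikes, ev, window = c(-1, 1), outBin = 0.1)
  se <- sd(rowMeans(rm2$rates)) / sqrt(nrow(rm2$rates))
  expect_lt(abs(mean(rm2$rates) - 10), 3 * se + 0.2)

  expect_error(estimateRates(1, 1, outBin = 0.03), "multiple")
})

test_that("onset-modulation testing flags ramps and spares the baseline", {
  set.seed(11)
  nTrials <- 40
  centers <- seq(-0.95, 0.95, by = 0.1)
  # null units: iid rates in every bin
  nullUnits <- replicate(30, matrix(rnorm(nTrials * 20, 10, 2), nTrials, 20),
                         simplify = FALSE)
  mf <- modulatedFraction(nullUnits, centers)
  expect_equal(mf$fraction[mf$baseline_bin], 0)   # identical pairs -> p = 1
  expect_lt(mean(mf$fraction[-mf$baseline_bin]), 0.15)

  # ramp units: rate rises in the last pre-onset bins
  rampUnits <- replicate(10, {
    base <- matrix(rnorm(nTrials * 20, 10, 2), nTrials, 20)
    ramp <- pmax(0, centers + 0.6) * 10
    base + matrix(ramp, nTrials, 20, byrow = TRUE)
  }, simplify = FALSE)
  mfr <- modulatedFraction(rampUnits, centers)
  preBins <- which(centers > -0.4 & centers < 0)
  expect_true(all(mfr$fraction[preBins] == 1))

  # constant rates: zero-variance differences give p = 1 everywhere
  const <- list(matrix(7, nTrials, 20))
  expect_true(all(modulatedFraction(const, centers)$fraction == 0))
})

test_that("speed tuning recovers exact linear rate dependence", {
  fps <- 80
  centers <- seq(60, 300, by = 20)
  framesPerBin <- 800                       # 10 s occupancy per bin
  speed <- rep(centers, each = framesPerBin)
  walking <- rep(TRUE, length(speed))
  # spike count in each bin exactly proportional to its centre speed
  spikes <- unlist(lapply(seq_along(centers), function(k) {
    f0 <- (k - 1) * framesPerBin
    n <- centers[k]                         # rate 0.1*centre Hz * 10 s
    (f0 / fps) + seq(0.001, framesPerBin / fps - 0.001, length.out = n)
  }))
  st <- speedTuning(spikes, speed, walking, fps)
  expect_length(st$centers, 13L)
  expect_false(st$excluded)
  expect_equal(st$r_squared, 1, tolerance = 1e-9)
  expect_lt(st$p_value, 1e-10)

  # too few occupied bins: excluded
  st2 <- speedTuning(spikes[1:5], rep(70, 1000), rep(TRUE, 1000), fps)
  expect_true(st2$excluded)
  expect_true(is.na(st2$r_squared))
})

test_that("speed-independent firing shows weak, rarely significant tuning", {
  set.seed(21)
  fps <- 80
  nFrames <- 80 * 400
  speed <- runif(nFrames, 50, 310)
  walking <- rep(TRUE, nFrames)
  res <- replicate(40, {
    spikes <- sort(runif(rpois(1, 8 * 400), 0, 400))
    st <- speedTuning(spikes, speed, walking, fps)
    c(st$r_squared, st$p_value)
  })
  expect_lt(mean(res[1, ]), 0.15)
  expect_lt(mean(res[2, ] < 0.05), 0.2)
})

test_that("vector length hits its bounds and the von Mises oracle", {
  ph <- idealPhase(600)
  # all spikes at one phase: r = 1
  oneBin <- which(ph >= 90 & ph < 105)
  spikes1 <- (oneBin[1:500] - 0.5) / 80
  pl1 <- phaseLocking(spikes1, ph)
  expect_equal(pl1$r, 1, tolerance = 1e-12)

  # equal counts in all 24 bins with uniform occupancy: r = 0
  binStarts <- seq(0, 345, by = 15)
  frames <- vapply(binStarts, function(b) which(ph >= b & ph < b + 15)[1],
                   integer(1))
  spikes0 <- sort((frames - 0.5) / 80)
  pl0 <- phaseLocking(spikes0, ph)
  expect_lt(pl0$r, 1e-12)

  # kappa = 1 intensity: r -> I1(1)/I0(1), the numeric-integration value
  spikesVM <- spikesFromPhase(ph, kappa = 1, prefDeg = 90, base = 20)
  plv <- phaseLocking(spikesVM, ph)
  oracle <- besselI(1, 1) / besselI(1, 0)
  expect_lt(abs(plv$r - oracle), 0.02)
  expect_lt(abs(circDiffDeg(plv$preferred_phase, 90)), 5)

  # no spikes during walking: flagged
  plNA <- phaseLocking(numeric(0), ph)
  expect_true(is.na(plNA$r))
})

test_that("binned vector length matches the unbinned spike resultant", {
  ph <- idealPhase(600)
  spikes <- spikesFromPhase(ph, kappa = 1.5, prefDeg = 220, base = 15)
  expect_gt(length(spikes), 1000)
  pl <- phaseLocking(spikes, ph)
  # unbinned oracle: resultant over per-spike phases (uniform occupancy)
  sp <- ph[floor(spikes * 80) + 1]
  un <- circResultant(sp)
  expect_lt(abs(pl$r - un$r), 0.02)
  expect_lt(abs(circDiffDeg(pl$preferred_phase, un$mu)), 5)
})

test_that("vector length is rotation-invariant", {
  ph <- idealPhase(200)
  spikes <- spikesFromPhase(ph, kappa = 2, prefDeg = 10, base = 10)
  pl <- phaseLocking(spikes, ph)
  # rotations commensurate with the 15-degree bins commute with binning
  for (rot in c(45, 135, 300)) {
    plr <- phaseLocking(spikes, wrapDeg(ph + rot))
    expect_equal(plr$r, pl$r, tolerance = 1e-9)
    expect_lt(abs(circDiffDeg(plr$preferred_phase, pl$preferred_phase + rot)),
              1e-6)
  }
})

test_that("median vector length increases with concentration", {
  ph <- idealPhase(400)
  rs <- vapply(c(0, 0.5, 1, 2, 4), function(k) {
    median(vapply(1:3, function(s)
      phaseLocking(spikesFromPhase(ph, k, 90, 12, seed = 100 + s), ph)$r,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("jitter surrogates gate locking decisions", {
  ph <- idealPhase(300)
  spikes <- spikesFromPhase(ph, kappa = 4, prefDeg = 45, base = 8)

  # zero jitter: every surrogate equals the actual r, so never locked
  jt0 <- jitterTest(spikes, ph, jitter = 0, nIter = 50)
  expect_true(all(abs(jt0$null - jt0$r) < 1e-12))
  expect_false(jt0$is_locked)

  # strong coupling at >= 500 strides: locked across seeds
  locked <- vapply(1:3, function(s)
    jitterTest(spikes, ph, nIter = 200, seed = s)$is_locked, logical(1))
  expect_true(all(locked))

  # uniform unit: not locked (single-seed smoke; size is calibrated in the
  # acceptance suite)
  uni <- spikesFromPhase(ph, kappa = 0, base = 8)
  jtU <- jitterTest(uni, ph, nIter = 200, seed = 2)
  expect_lt(jtU$r, jtU$threshold * 2)
})

test_that("per-unit statistics table covers all limbs and flags", {
  ses <- miniSessionFixture()
  seg <- fixture("miniseg", function() segmentSession(miniSessionFixture()))
  tab <- unitStats(ses, seg, seed = 1, jitterIterations = 100)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("R2", "speed_p", "r_LF", "r_RR", "locked_any") %in%
                    names(tab)))
  expect_true(all(tab$r_LF >= 0 & tab$r_LF <= 1, na.rm = TRUE))
  # the strongly phase-tuned unit has the largest preferred-limb r
  rLR <- tab$r_LR
  expect_equal(which.max(rLR), 2L)
})
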