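mkKin <- function(n, fill = 0) {
  kin <- data.frame(frame = 0:(n - 1L))
  for (col in c("nose_x", "nose_y", "tail_x", "tail_y", "lf_x", "lf_y",
                "rf_x", "rf_y", "lr_x", "lr_y", "rr_x", "rr_y"))
    kin[[col]] <- rep(fill, n)
  kin$nose_x <- kin$nose_x + 35; kin$tail_x <- kin$tail_x - 35
  kin
}

test_that("Savitzky-Golay smoothing reproduces polynomials and cuts noise", {
  n <- 400
  kin <- mkKin(n)
  x <- seq_len(n)
  kin$lf_x <- 0.001 * x^3 - 0.05 * x^2 + 2 * x - 7    # cubic: invariant
  kin$rf_x <- 5                                        # constant: invariant
  set.seed(1)
  noise <- rnorm(n, 0, 0.5)
  kin$lr_x <- 0.2 * x + noise                          # line + white noise
  ses <- GaitSession("s", kin)
  sm <- kinematics(smoothPositions(ses))
  expect_lt(max(abs(sm$lf_x - kin$lf_x)), 1e-9)
  expect_lt(max(abs(sm$rf_x - 5)), 1e-12)
  # a window spanning a full stride quarter-cycle halves white noise
  smW <- kinematics(smoothPositions(ses, window = 25))
  resid <- smW$lr_x - 0.2 * x
  expect_lt(sd(resid[30:(n - 30)]), sd(noise) / 2)
  expect_error(smoothPositions(ses, window = 3), "polyorder")
})

test_that("body speed is the RMS of the four limb speeds", {
  n <- 100
  kin <- mkKin(n)
  step <- 100 / 80                       # 100 mm/s at 80 fps
  for (col in c("lf_x", "rf_x", "lr_x", "rr_x"))
    kin[[col]] <- step * (0:(n - 1))
  ses <- GaitSession("s", kin)
  expect_equal(bodySpeed(ses), rep(100, n))

  kin2 <- mkKin(n)
  kin2$lf_x <- step * (0:(n - 1)); kin2$rf_x <- step * (0:(n - 1))
  expect_equal(bodySpeed(GaitSession("s", kin2)),
               rep(sqrt((100^2 + 100^2) / 4), n), tolerance = 1e-12)

  expect_equal(bodySpeed(GaitSession("s", mkKin(n))), rep(0, n))
})

test_that("bout detection keys on acceleration-peak prominence", {
  fps <- 80
  # strong bout: rest, sharp rise to 150 mm/s, 2 s plateau, stop
  v <- c(numeric(80), seq(0, 150, length.out = 4), rep(150, 160), numeric(80))
  bouts <- detectBouts(v, fps)
  expect_equal(nrow(bouts), 1L)
  accel <- c(0, (v[3:length(v)] - v[1:(length(v) - 2)]) * fps / 2, 0)
  expect_equal(bouts$onset_frame + 1L, which.max(accel))
  expect_gt(bouts$peak_prominence, 1000)

  # sub-threshold prominence: slow ramp to a sustained plateau
  vSlow <- c(numeric(80), seq(0, 60, length.out = 200), rep(60, 160),
             numeric(80))
  accelSlow <- c(0, (vSlow[3:length(vSlow)] - vSlow[1:(length(vSlow) - 2)]) *
                   fps / 2, 0)
  expect_lt(max(accelSlow), 1000)       # construction check
  expect_equal(nrow(detectBouts(vSlow, fps)), 0L)

  # 0.8 s bout: too short
  vShort <- c(numeric(80), seq(0, 150, length.out = 4), rep(150, 60),
              numeric(80))
  expect_equal(nrow(detectBouts(vShort, fps)), 0L)
})

test_that("bouts closer than 1 s keep the earlier one", {
  fps <- 80
  burst <- c(seq(0, 150, length.out = 4), rep(150, 100))
  v <- c(numeric(80), burst, numeric(40), burst, numeric(80))
  bouts <- detectBouts(v, fps)
  expect_equal(nrow(bouts), 1L)
  expect_lt(bouts$onset_frame, 90)
})

test_that("gait band-pass keeps stride frequencies and kills drift", {
  fps <- 80
  t <- seq(0, 10, by = 1 / fps)
  x <- sin(2 * pi * 2.5 * t)
  y <- bandpassGait(x, fps)
  mid <- y[(length(y) / 4):(3 * length(y) / 4)]
  expect_lt(abs(max(mid) - 1), 0.05)

  drift <- 10 * sin(2 * pi * 0.05 * t)
  yd <- bandpassGait(drift + x, fps)
  # residual drift power at least 20 dB down
  slow <- yd - bandpassGait(x, fps)
  expect_lt(sqrt(mean(slow^2)) / sqrt(mean(drift^2)), 0.1)

  expect_lt(max(abs(bandpassGait(rep(3, 800), fps))), 1e-6)
  expect_error(bandpassGait(rep(0, 10), fps), "too short")
})

test_that("stride segmentation finds alternating stance/swing at the period", {
  fps <- 80
  t <- seq(0, 4, by = 1 / fps)
  x <- -cos(2 * pi * 2.5 * t)
  st <- segmentStrides(x, onsetFrame = 0L, limb = "LF", frameRate = fps)
  expect_gte(nrow(st), 8); expect_lte(nrow(st), 10)
  expect_true(all(st$stance_onset_frame < st$swing_onset_frame))
  expect_true(all(st$swing_onset_frame < st$end_frame))
  iv <- diff(st$stance_onset_frame)
  expect_true(all(abs(iv - 32) <= 1))
  expect_equal(median(st$duration_s), 0.4, tolerance = 0.04)

  expect_equal(nrow(segmentStrides(seq_len(100), limb = "LF")), 0L)
})

test_that("limb phase advances linearly and respects sign inversion", {
  fps <- 80
  t <- seq(0, 8 - 1 / fps, by = 1 / fps)
  x <- -cos(2 * pi * 2.5 * t)          # minima at t = 0, 0.4, ...
  ph <- limbPhase(x)
  inner <- 81:560
  # linear advance: unwrapped phase increments constant at 360 * f / fps
  incs <- circDiffDeg(ph[inner + 1], ph[inner])
  expect_lt(max(abs(incs - 360 * 2.5 / fps)), 2)
  # minima sit at 0 degrees
  minIdx <- which(t %in% c(2, 2.4, 2.8))
  expect_lt(max(abs(circDiffDeg(ph[minIdx], 0))), 5)
  # sign flip shifts phase by half a cycle
  ph2 <- limbPhase(-x)
  expect_lt(max(abs(circDiffDeg(ph2[inner], ph[inner] + 180))), 1)
  expect_error(limbPhase(rep(0, 100)), "constant")
})

test_that("bouts and strides are recovered from synthetic sessions", {
  w <- walkFixture()
  truth <- w$truth; seg <- w$seg
  err <- vapply(truth$bouts$onset_frame, function(o)
    min(abs(seg$bouts$onset_frame - o)), numeric(1))
  expect_gte(mean(err <= 25), 0.9)               # detection rate
  expect_lte(median(err), 3)                     # onset accuracy

  ph <- truth$phase$LF
  truthStance <- truth$phase$frame[which(diff(ph) < -180) + 1L]
  det <- seg$strides$stance_onset_frame[seg$strides$limb == "LF"]
  derr <- vapply(det, function(d) min(abs(truthStance - d)), numeric(1))
  expect_gte(mean(derr <= 2), 0.95)
})

test_that("each stride has one swing onset and full phase coverage", {
  w <- walkFixture()
  st <- w$seg$strides
  # alternation is structural: one swing strictly inside every stride
  expect_true(all(st$stance_onset_frame < st$swing_onset_frame &
                  st$swing_onset_frame < st$end_frame))
  # phase visits all 12 30-degree bins within accepted strides
  cover <- vapply(seq_len(nrow(st)), function(i) {
    fr <- (st$stance_onset_frame[i] + 1L):st$end_frame[i]
    ph <- w$seg$phase[[st$limb[i]]][fr]
    length(unique(floor(ph / 30))) == 12
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  # phase at detected stance onsets clusters at the stance reference
  for (limb in c("LF", "RR")) {
    det <- st$stance_onset_frame[st$limb == limb]
    phd <- w$seg$phase[[limb]][det + 1L]
    expect_lt(abs(circDiffDeg(circMeanDeg(phd), 0)), 15)
  }
})
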