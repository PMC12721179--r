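test_that("error metrics match closed forms and enumeration", {
  cvT <- seq(-1.4, 1.4, by = 0.2)
  expect_equal(errorMetrics(1:15, 1:15, "time", cvT)$metric, 0)
  expect_equal(errorMetrics(c(1, 3), c(2, 5), "time", cvT)$metric,
               sqrt(mean(c(0.2, 0.4)^2)))

  cvP <- seq(15, 345, by = 30)
  expect_equal(errorMetrics(1:12, 1:12, "phase", cvP)$metric, 0)
  # wrap: 345 deg vs 15 deg differ by 30, not 330
  expect_equal(errorMetrics(12, 1, "phase", cvP)$metric, 30)
  expect_equal(circAbsDiffDeg(350, 10), 20)

  # uniform random predictions over 12 bins: exact expected MAE from the
  # 144-pair enumeration
  pairs <- expand.grid(a = 1:12, p = 1:12)
  enum <- mean(circAbsDiffDeg(cvP[pairs$a], cvP[pairs$p]))
  expect_equal(enum, 90)
  expect_equal(errorMetrics(pairs$a, pairs$p, "phase", cvP)$metric, 90)

  expect_error(errorMetrics(1:3, 1:2, "time", cvT), "length")
})

test_that("one-against-one ensembles have C(K,2) members and separate", {
  tt <- separableTensor("time", nTrials = 4)
  x <- do.call(rbind, lapply(1:15, function(k) tt@rates[, , k]))
  y <- rep(1:15, each = 4)
  fit <- fitOvoSvm(x, y, 15)
  expect_length(fit$models, 105L)
  expect_equal(predictVote(fit, x), y)     # training accuracy 1.0

  tp <- separableTensor("phase", nTrials = 4)
  xp <- do.call(rbind, lapply(1:12, function(k) tp@rates[, , k]))
  fit12 <- fitOvoSvm(xp, rep(1:12, each = 4), 12)
  expect_length(fit12$models, 66L)

  expect_error(fitOvoSvm(x[1:7, ], c(1, 1, 2, 2, 2, 2, 3), 3),
               "class 3 has fewer than 2")
})

test_that("majority vote is deterministic and agrees with a reference
           multiclass SVM on separated classes", {
  tt <- separableTensor("speed", nTrials = 6, sdNoise = 0.3)
  x <- do.call(rbind, lapply(1:4, function(k) tt@rates[, , k]))
  y <- rep(1:4, each = 6)
  fit <- fitOvoSvm(x, y, 4)
  p1 <- predictVote(fit, x)
  p2 <- predictVote(fit, x)
  expect_identical(p1, p2)
  # e1071's own internal one-vs-one vote as an independent reference
  ref <- as.integer(as.character(predict(
    e1071::svm(scale(x), factor(y), kernel = "radial", cost = 10,
               gamma = fit$gamma, scale = FALSE),
    scale(x))))
  expect_gte(mean(p1 == ref), 0.95)
  # class centroids classify to their class
  cent <- t(vapply(1:4, function(k) colMeans(x[y == k, ]), numeric(ncol(x))))
  expect_equal(predictVote(fit, cent), 1:4)
})

test_that("decoder evaluation is exact on separable data and deterministic", {
  tt <- separableTensor("time", nTrials = 8)
  cfg <- reducedConfig()
  res <- evaluateDecoder(tt, cfg, nUnits = 6, nDraws = 2, nIterations = 4,
                         seed = 5)
  expect_s4_class(res, "DecodingResult")
  expect_equal(rowSums(confusionMatrix(res)), rep(1, 15), tolerance = 1e-9)
  expect_equal(overallAccuracy(res), 1)
  expect_equal(errorMetric(res), 0)
  expect_equal(overallAccuracy(res), mean(classAccuracy(res)))

  res2 <- evaluateDecoder(tt, cfg, nUnits = 6, nDraws = 2, nIterations = 4,
                          seed = 5)
  expect_identical(res, res2)                       # bitwise reproducible
  expect_error(evaluateDecoder(tt, cfg, nUnits = 60), "exceeds")
})

test_that("pre/post summaries average the three bins of each window", {
  tt <- separableTensor("time", nTrials = 8)
  res <- evaluateDecoder(tt, reducedConfig(), nUnits = 6, nDraws = 1,
                         nIterations = 3, seed = 1)
  cv <- res@classValues
  expect_equal(sum(cv >= -0.9 & cv <= -0.3), 3L)
  expect_equal(sum(cv >= 0.3 & cv <= 0.9), 3L)
  pp <- prePostSummary(res)
  expect_equal(pp$pre, mean(classAccuracy(res)[cv >= -0.9 & cv <= -0.3]))
  # flat accuracy implies pre == post
  expect_equal(pp$pre, pp$post)

  resP <- evaluateDecoder(separableTensor("phase"), reducedConfig(),
                          nUnits = 6, nDraws = 1, nIterations = 2, seed = 1)
  expect_error(prePostSummary(resP), "time task")
})

test_that("shuffled labels decode at chance", {
  tt <- nullTensor("speed", nTrials = 12)
  cfg <- reducedConfig()
  sn <- shuffleNull(tt, cfg, nShuffles = 10, nUnits = 8, nIterations = 4,
                    seed = 3)
  expect_equal(dim(sn$band), c(2L, 4L))
  center <- mean(sn$overall)
  expect_gt(center, 0.5 / 4); expect_lt(center, 2 / 4)
  # the unshuffled accuracy of a zero-information tensor sits near chance
  res <- evaluateDecoder(tt, cfg, nUnits = 8, nDraws = 2, nIterations = 4,
                         seed = 9)
  expect_lt(abs(overallAccuracy(res) - 0.25), 0.25)
})

test_that("size sweep evaluates each feasible population size", {
  tt <- separableTensor("speed", nTrials = 8, nUnits = 10)
  cfg <- reducedConfig()
  expect_warning(
    sizeSweep(tt, cfg, sizes = c(5, 10, 50), nDraws = 1, nIterations = 1,
              seed = 2),
    "available units")
  sw <- suppressWarnings(
    sizeSweep(tt, cfg, sizes = c(5, 10, 50), nDraws = 2, nIterations = 2,
              seed = 2))
  expect_equal(sw$size, c(5, 10))
  expect_true(all(sw$mean_accuracy >= 0 & sw$mean_accuracy <= 1))

  sw1 <- sizeSweep(tt, cfg, sizes = 10, nDraws = 2, nIterations = 2, seed = 2)
  expect_equal(nrow(sw1), 1L)
})

test_that("trial tensors respect task geometry, quotas and pooling", {
  w <- walkFixture()
  ses <- w$session
  set.seed(77)
  ses@units <- lapply(1:5, function(i)
    generateSpikes(ses, tuningProfile(baseline_rate = 10, phase_kappa = 1),
                   seed = 30 + i, unitId = sprintf("q-u%d", i), region = "DLS"))
  cfg <- reducedConfig()
  cfg$quota_time <- 10; cfg$quota_phase <- 30; cfg$quota_speed <- 20

  tt <- buildTrials(list(ses), list(w$seg), "time", cfg, seed = 1)
  expect_equal(dim(tt@rates), c(10L, 5L, 15L))
  expect_equal(tt@classValues, seq(-1.4, 1.4, by = 0.2))

  ts <- buildTrials(list(ses), list(w$seg), "speed", cfg, seed = 1)
  expect_equal(dim(ts@rates)[c(1, 3)], c(20L, 4L))
  expect_equal(ts@classValues, c(75, 125, 175, 225))

  tp <- buildTrials(list(ses), list(w$seg), "phase", cfg, seed = 1, limb = "RF")
  expect_equal(dim(tp@rates)[3], 12L)

  # pooling two copies doubles the unit axis, keeps the trial count
  t2 <- buildTrials(list(ses, ses), list(w$seg, w$seg), "time", cfg, seed = 1)
  expect_equal(dim(t2@rates)[2], 10L)
  expect_equal(dim(t2@rates)[1], 10L)

  # unmeetable quota: session excluded, then error when none remain
  cfg$quota_time <- 10000
  expect_warning(expect_error(
    buildTrials(list(ses), list(w$seg), "time", cfg, seed = 1), "quota"),
    "excluded")
})
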