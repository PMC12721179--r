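SPEED_CLASS_EDGES <- c(50, 100, 150, 200, 250)

# Session-wide smoothed rate grid: counts in baseBin bins over [0, duration],
# Gaussian-smoothed; returns bins x units matrix in Hz plus the bin edges.
sessionRateGrid <- function(session, baseBin = 0.025, kernelSd = 0.1) {
  dur <- duration(session)
  nBins <- floor(dur / baseBin)
  edges <- (0:nBins) * baseBin
  rates <- vapply(units(session), function(u) {
    st <- spikeTimes(u)
    st <- st[st < edges[nBins + 1L]]
    counts <- if (length(st))
      tabulate(findInterval(st, edges), nbins = nBins) else numeric(nBins)
    gaussSmooth(counts, baseBin, kernelSd) / baseBin
  }, numeric(nBins))
  list(rates = matrix(rates, nrow = nBins), edges = edges, baseBin = baseBin)
}

# Per-session trial x units x classes array for one task, before pooling.
sessionTrialArray <- function(session, seg, task, config, limb = "LR") {
  fps <- frameRate(session)
  dur <- duration(session)
  if (task == "time") {
    w <- config$decode_window
    onsets <- (seg$bouts$onset_frame + 1) / fps
    onsets <- onsets[onsets - w > 0 & onsets + w < dur]
    if (!length(onsets)) return(NULL)
    K <- as.integer(round(2 * w / config$time_bin))
    arr <- array(0, c(length(onsets), length(units(session)), K))
    for (u in seq_along(units(session))) {
      rm <- estimateRates(units(session)[[u]], onsets, window = c(-w, w),
                          kernelSd = config$kernel_sd,
                          baseBin = config$base_bin, outBin = config$time_bin)
      arr[, u, ] <- rm$rates
    }
    return(list(rates = arr,
                classValues = -w + (seq_len(K) - 0.5) * config$time_bin))
  }

  grid <- sessionRateGrid(session, config$base_bin, config$kernel_sd)
  frameTime <- (kinematics(session)$frame + 0.5) / fps
  frameGridBin <- pmin(nrow(grid$rates),
                       floor(frameTime / config$base_bin) + 1L)
  walking <- logical(nrow(kinematics(session)))
  for (b in seq_len(nrow(seg$bouts)))
    walking[(seg$bouts$onset_frame[b] + 1L):(seg$bouts$offset_frame[b] + 1L)] <- TRUE

  if (task == "speed") {
    # non-overlapping 0.2 s walking bins labelled by their mean body speed
    binLen <- as.integer(round(config$time_bin * fps))
    nWin <- floor(length(walking) / binLen)
    samples <- vector("list", length(SPEED_CLASS_EDGES) - 1L)
    for (wI in seq_len(nWin)) {
      fr <- ((wI - 1L) * binLen + 1L):(wI * binLen)
      if (!all(walking[fr])) next
      v <- mean(seg$speed[fr])
      cls <- findInterval(v, SPEED_CLASS_EDGES)
      if (cls < 1 || cls > 4 || v >= SPEED_CLASS_EDGES[5]) next
      vec <- colMeans(grid$rates[frameGridBin[fr], , drop = FALSE])
      samples[[cls]] <- c(samples[[cls]], list(vec))
    }
    nPer <- vapply(samples, length, integer(1))
    if (any(nPer == 0L)) return(NULL)
    nTrials <- min(nPer)
    arr <- array(0, c(nTrials, length(units(session)), 4L))
    for (k in 1:4) for (t in seq_len(nTrials))
      arr[t, , k] <- samples[[k]][[t]]
    return(list(rates = arr,
                classValues = SPEED_CLASS_EDGES[-5] + 25))
  }

  if (task == "phase") {
    K <- config$phase_classes
    width <- 360 / K
    centers <- (seq_len(K) - 0.5) * width
    ph <- seg$phase[[limb]]
    st <- seg$strides[seg$strides$limb == limb, , drop = FALSE]
    rows <- list()
    for (s in seq_len(nrow(st))) {
      fr <- (st$stance_onset_frame[s] + 1L):(st$end_frame[s])
      bins <- floor(ph[fr] / width) + 1L
      bins[bins > K] <- K
      if (any(is.na(bins)) || length(unique(bins)) < K) next
      mat <- matrix(0, K, ncol(grid$rates))
      for (k in seq_len(K))
        mat[k, ] <- colMeans(grid$rates[frameGridBin[fr[bins == k]], ,
                                        drop = FALSE])
      rows <- c(rows, list(mat))
    }
    if (!length(rows)) return(NULL)
    arr <- array(0, c(length(rows), ncol(grid$rates), K))
    for (t in seq_along(rows)) arr[t, , ] <- t(rows[[t]])
    return(list(rates = arr, classValues = centers))
  }
  stop("unknown task: ", task)
}

#' Build a decoder-ready trial tensor from segmented sessions
#'
#' Constructs per-session trials for one task, enforces the per-session
#' trial quota by seeded random selection (sessions below quota are
#' excluded with a warning), and pools units across sessions into a
#' pseudo-population by concatenating unit axes at matching trial index.
#'
#' Tasks: \code{"time"} — each walking bout contributes 15 population
#' vectors, one per 0.2 s bin of the plus/minus 1.5 s onset window;
#' \code{"speed"} — each trial is a fully-walking 0.2 s bin labelled by
#' one of the four 50 mm/s speed classes (50-250 mm/s), balanced across
#' classes; \code{"phase"} — each trial is one stride of \code{limb}, its
#' 12 vectors the smoothed rates averaged over the frames of each
#' 30-degree phase bin.
#'
#' @param sessions list of \linkS4class{GaitSession}.
#' @param segs parallel list of [segmentSession()] outputs.
#' @param task \code{"time"}, \code{"speed"} or \code{"phase"}.
#' @param config configuration list (see [defaultConfig()]).
#' @param seed integer seed for trial selection.
#' @param quota per-session trial quota; defaults from config
#'   (time 50, speed 100 per class, phase 200 strides).
#' @param limb decoded limb for the phase task.
#' @return A \linkS4class{TrialTensor}.
#' @export
buildTrials <- function(sessions, segs, task, config = defaultConfig(),
                        seed = 1, quota = NULL, limb = "LR") {
  stopifnot(length(sessions) == length(segs))
  if (is.null(quota))
    quota <- switch(task, time = config$quota_time,
                    speed = config$quota_speed, phase = config$quota_phase)
  picked <- list(); unitIds <- character(0); sessionIds <- character(0)
  classValues <- NULL
  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    ta <- sessionTrialArray(ses, segs[[i]], task, config, limb)
    if (is.null(ta) || dim(ta$rates)[1] < quota) {
      warning("session '", sessionId(ses), "' below ", task,
              " quota (needs ", quota, "); excluded", call. = FALSE)
      next
    }
    set.seed(deriveSeed(seed, paste0("trials/", task, "/", sessionId(ses))))
    sel <- sort(sample(dim(ta$rates)[1], quota))
    picked <- c(picked, list(ta$rates[sel, , , drop = FALSE]))
    unitIds <- c(unitIds, vapply(units(ses), unitId, character(1)))
    sessionIds <- c(sessionIds,
                    rep(sessionId(ses), length(units(ses))))
    classValues <- ta$classValues
  }
  if (!length(picked))
    stop("no session meets the ", task, " trial quota of ", quota)
  K <- dim(picked[[1]])[3]
  arr <- array(0, c(quota, length(unitIds), K))
  off <- 0L
  for (p in picked) {
    arr[, off + seq_len(dim(p)[2]), ] <- p
    off <- off + dim(p)[2]
  }
  new("TrialTensor", task = task, rates = arr, classValues = classValues,
      unitIds = unitIds, sessionIds = sessionIds)
}

# ---- one-against-one SVM ensemble -----------------------------------------

medianHeuristicGamma <- function(x, maxRows = 200L) {
  if (nrow(x) > maxRows) x <- x[seq(1, nrow(x), length.out = maxRows), , drop = FALSE]
  d2 <- as.numeric(stats::dist(x))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) med <- ncol(x)
  1 / med
}

#' Train a one-against-one SVM ensemble
#'
#' Trains one binary radial-basis-kernel SVM per unordered pair of classes
#' — C(K, 2) classifiers, e.g. 105 for the 15 time bins. Features are
#' standardised per unit with training-set statistics; the kernel
#' bandwidth defaults to the median-heuristic scale of the standardised
#' training set. When \code{tune = TRUE}, cost and bandwidth are selected
#' by seeded 5-fold cross-validation of the full ensemble over a fixed
#' grid (cost 0.1/1/10/100 x bandwidth scale 0.1/0.3/1/3/10), enumerated
#' in order and capped at \code{maxEvaluations} candidate evaluations.
#'
#' @param x training matrix, samples x units (Hz).
#' @param y integer class labels in 1..K.
#' @param K number of classes.
#' @param cost SVM cost parameter (used when not tuning).
#' @param gammaScale multiplier on the median-heuristic kernel bandwidth.
#' @param tune run the cross-validated grid search.
#' @param maxEvaluations cap on tuning evaluations.
#' @param seed integer seed (fold assignment during tuning).
#' @return An object of class \code{ovoSvm}: list with the binary models,
#'   class pairs, scaling and kernel parameters.
#' @export
fitOvoSvm <- function(x, y, K = max(y), cost = 10, gammaScale = 1,
                      tune = FALSE, maxEvaluations = 20, seed = 1) {
  stopifnot(nrow(x) == length(y), all(y >= 1 & y <= K))
  tab <- tabulate(y, nbins = K)
  if (any(tab < 2))
    stop("class ", which(tab < 2)[1], " has fewer than 2 training trials")
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xs <- scale(x, ctr, sdv)
  gammaBase <- medianHeuristicGamma(xs)

  if (tune) {
    grid <- expand.grid(gammaScale = c(0.1, 0.3, 1, 3, 10),
                        cost = c(0.1, 1, 10, 100))
    grid <- grid[seq_len(min(nrow(grid), maxEvaluations)), ]
    set.seed(deriveSeed(seed, "svm-tune"))
    folds <- sample(rep_len(1:5, nrow(xs)))
    best <- -Inf
    for (g in seq_len(nrow(grid))) {
      acc <- 0
      for (f in 1:5) {
        tr <- folds != f
        if (min(tabulate(y[tr], nbins = K)) < 2) next
        fit <- fitOvoSvm(x[tr, , drop = FALSE], y[tr], K,
                         cost = grid$cost[g], gammaScale = grid$gammaScale[g],
                         tune = FALSE)
        acc <- acc + mean(predictVote(fit, x[!tr, , drop = FALSE]) == y[!tr])
      }
      if (acc > best) { best <- acc; cost <- grid$cost[g]; gammaScale <- grid$gammaScale[g] }
    }
  }

  pairs <- utils::combn(K, 2)
  models <- vector("list", ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    a <- pairs[1, m]; b <- pairs[2, m]
    idx <- y == a | y == b
    yf <- factor(y[idx], levels = c(a, b))
    models[[m]] <- e1071::svm(xs[idx, , drop = FALSE], yf,
                              kernel = "radial", cost = cost,
                              gamma = gammaBase * gammaScale, scale = FALSE)
  }
  structure(list(models = models, pairs = pairs, K = K, center = ctr,
                 sd = sdv, cost = cost, gamma = gammaBase * gammaScale),
            class = "ovoSvm")
}

#' Majority-vote prediction from a one-against-one ensemble
#'
#' Every binary classifier votes for one of its two classes; the predicted
#' class takes the majority of the C(K, 2) votes. Vote ties are broken by
#' the largest summed signed decision-function margin over the tied
#' classes' binary models; any residual tie goes to the lowest class
#' index, so prediction is deterministic.
#'
#' @param fit an \code{ovoSvm} from [fitOvoSvm()].
#' @param x test matrix, samples x units (raw Hz; training scaling is
#'   applied internally).
#' @return Integer vector of predicted classes in 1..K.
#' @export
predictVote <- function(fit, x) {
  stopifnot(inherits(fit, "ovoSvm"))
  x <- matrix(x, ncol = length(fit$center))
  xs <- scale(x, fit$center, fit$sd)
  n <- nrow(xs)
  votes <- matrix(0L, n, fit$K)
  margin <- matrix(0, n, fit$K)
  for (m in seq_along(fit$models)) {
    a <- fit$pairs[1, m]; b <- fit$pairs[2, m]
    pr <- stats::predict(fit$models[[m]], xs, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))  # positive favours class a
    win <- ifelse(dv >= 0, a, b)
    votes[cbind(seq_len(n), win)] <- votes[cbind(seq_len(n), win)] + 1L
    margin[, a] <- margin[, a] + dv
    margin[, b] <- margin[, b] - dv
  }
  vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) top <- top[order(-margin[i, top], top)]
    top[1L]
  }, integer(1))
}

#' Decoding error metrics
#'
#' Time and speed tasks: root-mean-squared error between the physical
#' class-centre values of actual and predicted labels (seconds or mm/s).
#' Phase task: mean absolute angular difference between actual and
#' predicted phase-bin centres, wrapped to [0, 180] degrees.
#'
#' @param actual,predicted integer class labels (1..K), equal length.
#' @param task \code{"time"}, \code{"speed"} or \code{"phase"}.
#' @param classValues physical class centres.
#' @return list with \code{metric} (RMSE or MAE in physical units) and
#'   \code{rmse_bins} (RMSE in bin counts; NA for phase).
#' @export
errorMetrics <- function(actual, predicted, task, classValues) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have the same length")
  if (task == "phase") {
    mae <- mean(circAbsDiffDeg(classValues[actual], classValues[predicted]))
    return(list(metric = mae, rmse_bins = NA_real_))
  }
  list(metric = sqrt(mean((classValues[actual] - classValues[predicted])^2)),
       rmse_bins = sqrt(mean((actual - predicted)^2)))
}

#' Evaluate a decoder on a trial tensor
#'
#' The paper-style nested evaluation: an outer loop of \code{nDraws}
#' seeded random draws of \code{nUnits} units, and an inner loop of
#' \code{nIterations} evaluation rounds, each holding out
#' \code{heldOut} random trial(s), training the one-against-one ensemble
#' on the rest and classifying the held-out population vectors. Results
#' are aggregated into a row-normalised confusion matrix, per-class and
#' overall accuracy, the task's error metric, and the per-draw accuracy
#' distribution.
#'
#' @param tensor a \linkS4class{TrialTensor}.
#' @param config configuration list (SVM settings; see [defaultConfig()]).
#' @param nUnits units per draw (task default from config when NULL).
#' @param nDraws outer random unit draws.
#' @param nIterations inner held-out evaluation rounds.
#' @param heldOut trials held out per round (task default when NULL).
#' @param seed integer seed; fixed seed plus inputs gives an identical
#'   result.
#' @return A \linkS4class{DecodingResult}.
#' @export
evaluateDecoder <- function(tensor, config = defaultConfig(), nUnits = NULL,
                            nDraws = config$n_draws,
                            nIterations = config$n_eval_iterations,
                            heldOut = NULL, seed = 1) {
  stopifnot(is(tensor, "TrialTensor"))
  task <- tensor@task
  if (is.null(nUnits))
    nUnits <- switch(task, time = config$n_units_time,
                     speed = config$n_units_speed,
                     phase = config$n_units_phase)
  if (is.null(heldOut))
    heldOut <- switch(task, time = config$held_out_time,
                      speed = config$held_out_speed,
                      phase = config$held_out_phase)
  d <- dim(tensor@rates)
  nTrials <- d[1]; U <- d[2]; K <- d[3]
  if (nUnits > U) stop("nUnits (", nUnits, ") exceeds available units (", U, ")")
  if (nTrials <= heldOut) stop("insufficient trials for held-out evaluation")

  confusion <- matrix(0, K, K)
  drawAcc <- numeric(nDraws)
  drawClassAcc <- matrix(0, nDraws, K)
  allActual <- integer(0); allPred <- integer(0)
  for (dr in seq_len(nDraws)) {
    set.seed(deriveSeed(seed, paste0("draw/", task, "/", dr)))
    unitSel <- sample(U, nUnits)
    drawConf <- matrix(0, K, K)
    for (it in seq_len(nIterations)) {
      testIdx <- sample(nTrials, heldOut)
      trainIdx <- setdiff(seq_len(nTrials), testIdx)
      xTrain <- do.call(rbind, lapply(seq_len(K), function(k)
        matrix(tensor@rates[trainIdx, unitSel, k], ncol = nUnits)))
      yTrain <- rep(seq_len(K), each = length(trainIdx))
      xTest <- do.call(rbind, lapply(seq_len(K), function(k)
        matrix(tensor@rates[testIdx, unitSel, k], ncol = nUnits)))
      yTest <- rep(seq_len(K), each = heldOut)
      fit <- fitOvoSvm(xTrain, yTrain, K, cost = config$svm_cost,
                       gammaScale = config$svm_gamma_scale,
                       tune = isTRUE(config$svm_tune), seed = seed)
      pred <- predictVote(fit, xTest)
      for (j in seq_along(yTest))
        drawConf[yTest[j], pred[j]] <- drawConf[yTest[j], pred[j]] + 1
      allActual <- c(allActual, yTest); allPred <- c(allPred, pred)
    }
    confusion <- confusion + drawConf
    rowN <- drawConf / pmax(rowSums(drawConf), 1)
    drawClassAcc[dr, ] <- diag(rowN)
    drawAcc[dr] <- mean(diag(rowN))
  }
  rowTot <- rowSums(confusion)
  confNorm <- confusion / pmax(rowTot, 1)
  em <- errorMetrics(allActual, allPred, task, tensor@classValues)
  new("DecodingResult", task = task, confusion = confNorm,
      classAccuracy = diag(confNorm), overallAccuracy = mean(diag(confNorm)),
      errorMetric = em$metric, errorMetricBins = em$rmse_bins,
      drawAccuracy = drawAcc, drawClassAccuracy = drawClassAcc,
      shuffleBand = matrix(numeric(0), 0, K), classValues = tensor@classValues,
      nUnits = as.integer(nUnits))
}

#' Shuffle-null confidence band for a decoder
#'
#' Repeats the evaluation on label-shuffled tensors in which, within each
#' trial, the class assignment of the population vectors is randomly
#' permuted (destroying the rate-class relationship while preserving each
#' trial's rate distribution). Returns the per-class 2.5/97.5 percentile
#' band of the shuffled accuracies, the empirical chance level.
#'
#' @param tensor a \linkS4class{TrialTensor}.
#' @param config configuration list.
#' @param nShuffles shuffled evaluations.
#' @param nUnits,nIterations,heldOut evaluation settings (single draw per
#'   shuffle).
#' @param seed integer seed.
#' @return list with \code{band} (2 x K matrix of class-accuracy
#'   percentiles), \code{overall} (per-shuffle overall accuracies) and
#'   \code{classAccuracy} (shuffles x K).
#' @export
shuffleNull <- function(tensor, config = defaultConfig(), nShuffles = 50,
                        nUnits = NULL, nIterations = 10, heldOut = NULL,
                        seed = 1) {
  stopifnot(is(tensor, "TrialTensor"))
  d <- dim(tensor@rates)
  K <- d[3]
  classAcc <- matrix(0, nShuffles, K)
  overall <- numeric(nShuffles)
  for (s in seq_len(nShuffles)) {
    set.seed(deriveSeed(seed, paste0("shuffle/", s)))
    shuf <- tensor
    for (t in seq_len(d[1])) {
      perm <- sample(K)
      shuf@rates[t, , ] <- tensor@rates[t, , perm]
    }
    res <- evaluateDecoder(shuf, config, nUnits = nUnits, nDraws = 1,
                           nIterations = nIterations, heldOut = heldOut,
                           seed = deriveSeed(seed, paste0("shuffle-eval/", s)))
    classAcc[s, ] <- res@classAccuracy
    overall[s] <- res@overallAccuracy
  }
  band <- apply(classAcc, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
  list(band = matrix(band, nrow = 2), overall = overall,
       classAccuracy = classAcc)
}

#' Pre-start and post-start mean decoding accuracy
#'
#' Averages the per-class accuracy of a time-task result over the three
#' bins whose centres fall in the preparatory window (-0.9 to -0.3 s
#' before onset) and the three bins in the performance window (+0.3 to
#' +0.9 s after onset).
#'
#' @param result a time-task \linkS4class{DecodingResult}.
#' @return list with \code{pre}, \code{post}, and the per-draw means
#'   \code{pre_draws}, \code{post_draws}.
#' @export
prePostSummary <- function(result) {
  stopifnot(is(result, "DecodingResult"))
  if (result@task != "time")
    stop("pre/post summary is defined for the time task only")
  cv <- result@classValues
  pre <- which(cv >= -0.9 & cv <= -0.3)
  post <- which(cv >= 0.3 & cv <= 0.9)
  list(pre = mean(result@classAccuracy[pre]),
       post = mean(result@classAccuracy[post]),
       pre_draws = rowMeans(result@drawClassAccuracy[, pre, drop = FALSE]),
       post_draws = rowMeans(result@drawClassAccuracy[, post, drop = FALSE]))
}

#' Decoding accuracy as a function of population size
#'
#' Re-evaluates the decoder at increasing unit-draw sizes (25, 50, 100,
#' 150, 200 by default); sizes exceeding the available units are dropped
#' with a warning.
#'
#' @param tensor a \linkS4class{TrialTensor}.
#' @param config configuration list.
#' @param sizes unit-draw sizes.
#' @param nDraws,nIterations,heldOut evaluation settings per size.
#' @param seed integer seed.
#' @return data.frame with \code{size}, \code{mean_accuracy},
#'   \code{sd_accuracy} over draws.
#' @export
sizeSweep <- function(tensor, config = defaultConfig(),
                      sizes = config$sweep_sizes, nDraws = config$n_draws,
                      nIterations = config$n_eval_iterations, heldOut = NULL,
                      seed = 1) {
  U <- dim(tensor@rates)[2]
  if (any(sizes > U)) {
    warning("dropping sweep sizes above the ", U, " available units",
            call. = FALSE)
    sizes <- sizes[sizes <= U]
  }
  if (!length(sizes)) stop("no feasible sweep size")
  rows <- lapply(sizes, function(sz) {
    res <- evaluateDecoder(tensor, config, nUnits = sz, nDraws = nDraws,
                           nIterations = nIterations, heldOut = heldOut,
                           seed = deriveSeed(seed, paste0("sweep/", sz)))
    data.frame(size = sz, mean_accuracy = mean(res@drawAccuracy),
               sd_accuracy = stats::sd(res@drawAccuracy))
  })
  do.call(rbind, rows)
}
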