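#' Smoothed peri-event firing rates
#'
#' Spike counts in 25 ms base bins around each event are convolved with a
#' Gaussian kernel (sd 0.1 s by default) and block-averaged into the output
#' bin width (0.1 s for modulation analysis, 0.2 s for decoding). Counting
#' is padded by four kernel sd beyond the window so kernel mass is
#' conserved at the window edges.
#'
#' @param spikes numeric spike times (s) or a \linkS4class{SpikeTrain}.
#' @param eventTimes event (e.g. bout onset) times, s.
#' @param window c(before, after) in s relative to the event, e.g.
#'   \code{c(-1, 1)}.
#' @param kernelSd Gaussian kernel sd, s.
#' @param baseBin base bin width, s.
#' @param outBin output bin width, s; must be an integer multiple of
#'   \code{baseBin}.
#' @return list with \code{rates} (trials x bins matrix, Hz),
#'   \code{centers} (bin centres, s) and \code{width} (s).
#' @export
estimateRates <- function(spikes, eventTimes, window = c(-1, 1),
                          kernelSd = 0.1, baseBin = 0.025, outBin = 0.1) {
  if (is(spikes, "SpikeTrain")) spikes <- spikeTimes(spikes)
  ratio <- outBin / baseBin
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("outBin must be an integer multiple of baseBin")
  ratio <- as.integer(round(ratio))
  pad <- ceiling(4 * kernelSd / baseBin) * baseBin
  edges <- seq(window[1] - pad, window[2] + pad + baseBin / 2, by = baseBin)
  nBase <- length(edges) - 1L
  inWin <- edges[-1] - baseBin / 2 > window[1] &
           edges[-1] - baseBin / 2 < window[2] + baseBin / 2
  nOut <- as.integer(round((window[2] - window[1]) / outBin))

  rates <- matrix(0, nrow = length(eventTimes), ncol = nOut)
  for (i in seq_along(eventTimes)) {
    rel <- spikes - eventTimes[i]
    rel <- rel[rel >= edges[1] & rel < edges[nBase + 1L]]
    counts <- if (length(rel))
      tabulate(findInterval(rel, edges), nbins = nBase) else numeric(nBase)
    sm <- gaussSmooth(counts, baseBin, kernelSd)[inWin]
    rates[i, ] <- colMeans(matrix(sm / baseBin, nrow = ratio))
  }
  centers <- window[1] + (seq_len(nOut) - 0.5) * outBin
  list(rates = rates, centers = centers, width = outBin)
}

#' Fraction of units modulated around walking onset
#'
#' For each unit and each 0.1 s bin, a two-sided paired t-test compares
#' firing rates across trials against the baseline bin (-1 to -0.9 s
#' before onset); a unit counts as modulated in a bin when p < alpha.
#' Zero-variance rate differences give p = 1 (no modulation). P-values
#' are deliberately uncorrected across bins.
#'
#' @param rateMatrices list (one per unit) of trials x bins rate matrices
#'   on a common bin grid, e.g. from [estimateRates()].
#' @param centers shared bin centres, s relative to onset.
#' @param baselineWindow c(lo, hi) in s; the bin whose centre falls inside
#'   is the baseline.
#' @param alpha per-bin significance level.
#' @return list with \code{fraction} (per-bin fraction of significant
#'   units), \code{pvalues} (units x bins), \code{centers} and
#'   \code{baseline_bin}.
#' @export
modulatedFraction <- function(rateMatrices, centers,
                              baselineWindow = c(-1, -0.9), alpha = 0.05) {
  baseBin <- which(centers >= baselineWindow[1] & centers <= baselineWindow[2])
  if (length(baseBin) != 1L)
    stop("baseline window must contain exactly one bin centre")
  nBins <- length(centers)
  p <- t(vapply(rateMatrices, function(rm) {
    stopifnot(ncol(rm) == nBins, nrow(rm) >= 2)
    base <- rm[, baseBin]
    vapply(seq_len(nBins), function(b) {
      d <- rm[, b] - base
      if (all(abs(d - d[1]) < 1e-12)) return(1)
      stats::t.test(rm[, b], base, paired = TRUE)$p.value
    }, numeric(1))
  }, numeric(nBins)))
  list(fraction = colMeans(p < alpha), pvalues = p, centers = centers,
       baseline_bin = baseBin)
}

#' Speed tuning of one unit during walking
#'
#' Body speed during walking frames is binned in 20 mm/s increments from
#' 50 to 310 mm/s (13 bins); the unit's mean firing rate in each occupied
#' bin (spike count over occupancy time) is correlated with the bin-centre
#' speed. The tuning strength is the squared Pearson correlation with its
#' two-sided p-value; units whose speed range covers fewer than three bins
#' are excluded.
#'
#' @param spikes spike times (s) or a \linkS4class{SpikeTrain}.
#' @param speed per-frame body speed, mm/s.
#' @param walkingMask logical per-frame mask of walking frames.
#' @param frameRate frames per second.
#' @param binWidth,binMin,binMax speed-bin layout, mm/s.
#' @return list with \code{centers}, \code{rate} (NA for unoccupied bins),
#'   \code{occupancy} (s), \code{r_squared}, \code{p_value},
#'   \code{n_bins_occupied} and \code{excluded}.
#' @export
speedTuning <- function(spikes, speed, walkingMask, frameRate = 80,
                        binWidth = 20, binMin = 50, binMax = 310) {
  if (is(spikes, "SpikeTrain")) spikes <- spikeTimes(spikes)
  stopifnot(length(speed) == length(walkingMask))
  edges <- seq(binMin, binMax, by = binWidth)
  nBins <- length(edges) - 1L
  centers <- edges[-1] - binWidth / 2

  frameBin <- findInterval(speed, edges, rightmost.closed = TRUE)
  frameBin[!walkingMask | frameBin < 1 | frameBin > nBins] <- NA
  occ <- tabulate(frameBin[!is.na(frameBin)], nbins = nBins) / frameRate

  sf <- floor(spikes * frameRate) + 1L
  sf <- sf[sf >= 1 & sf <= length(speed)]
  sb <- frameBin[sf]
  counts <- tabulate(sb[!is.na(sb)], nbins = nBins)

  rate <- ifelse(occ > 0, counts / pmax(occ, 1e-12), NA)
  occupied <- which(occ > 0)
  if (length(occupied) < 3L)
    return(list(centers = centers, rate = rate, occupancy = occ,
                r_squared = NA_real_, p_value = NA_real_,
                n_bins_occupied = length(occupied), excluded = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(rate[occupied], centers[occupied]))
  r2 <- unname(ct$estimate^2)
  if (!is.finite(r2)) r2 <- 0
  list(centers = centers, rate = rate, occupancy = occ,
       r_squared = r2,
       p_value = if (is.finite(ct$p.value)) ct$p.value else 1,
       n_bins_occupied = length(occupied), excluded = FALSE)
}

# Map spike times to the 15-degree phase bin of their containing video
# frame; returns NA for spikes outside walking frames. Shared by the
# phase-locking statistic and its jitter null.
spikePhaseBins <- function(spikes, phaseVec, frameRate, nBins) {
  sf <- floor(spikes * frameRate) + 1L
  ph <- rep(NA_real_, length(spikes))
  ok <- sf >= 1 & sf <= length(phaseVec)
  ph[ok] <- phaseVec[sf[ok]]
  bin <- floor(ph / (360 / nBins)) + 1L
  bin[bin > nBins] <- nBins   # guard phase == 360 after rounding
  bin
}

binnedVectorLength <- function(counts, occ, centersDeg) {
  w <- ifelse(occ > 0, counts / pmax(occ, 1e-12), 0)
  circResultant(centersDeg, w)
}

#' Spike-gait phase locking of one unit
#'
#' Spikes during walking are assigned the gait phase of their containing
#' video frame and counted in 24 bins of 15 degrees spanning the full
#' cycle. Bin rates are normalised by the time spent in each phase bin
#' (occupancy), and the mean vector length r (0 = uniform, 1 = perfectly
#' locked) and preferred phase are the modulus and argument of the
#' rate-weighted circular resultant over the bin centres.
#'
#' @param spikes spike times (s) or a \linkS4class{SpikeTrain}.
#' @param phaseVec per-frame phase of one limb, degrees (NA outside bouts).
#' @param frameRate frames per second.
#' @param nBins number of phase bins (24).
#' @return list with \code{bin_centers} (deg), \code{rate} (Hz per bin),
#'   \code{occupancy} (s), \code{r}, \code{preferred_phase} (deg) and
#'   \code{n_spikes} (spikes during walking). r is NA (unit flagged) when
#'   no spike falls in a walking frame.
#' @export
phaseLocking <- function(spikes, phaseVec, frameRate = 80, nBins = 24) {
  if (is(spikes, "SpikeTrain")) spikes <- spikeTimes(spikes)
  width <- 360 / nBins
  centers <- (seq_len(nBins) - 0.5) * width
  frameBin <- floor(phaseVec / width) + 1L
  frameBin[frameBin > nBins] <- nBins
  occ <- tabulate(frameBin[!is.na(frameBin)], nbins = nBins) / frameRate

  bins <- spikePhaseBins(spikes, phaseVec, frameRate, nBins)
  bins <- bins[!is.na(bins)]
  if (!length(bins))
    return(list(bin_centers = centers, rate = rep(NA_real_, nBins),
                occupancy = occ, r = NA_real_,
                preferred_phase = NA_real_, n_spikes = 0L))
  counts <- tabulate(bins, nbins = nBins)
  res <- binnedVectorLength(counts, occ, centers)
  list(bin_centers = centers,
       rate = ifelse(occ > 0, counts / pmax(occ, 1e-12), NA),
       occupancy = occ, r = res$r, preferred_phase = res$mu,
       n_spikes = length(bins))
}

#' Spike-jitter significance test for phase locking
#'
#' Builds a null distribution of the vector length by displacing each
#' spike independently by a uniform random amount within plus/minus
#' \code{jitter} seconds and recomputing r (default 1000 surrogates);
#' jittered spikes that land outside walking frames drop out of that
#' surrogate. The unit is locked to this limb when its actual r exceeds
#' the 95th percentile of the null.
#'
#' @param spikes spike times (s) or a \linkS4class{SpikeTrain}.
#' @param phaseVec per-frame phase of one limb, degrees (NA outside bouts).
#' @param frameRate frames per second.
#' @param jitter half-width of the jitter window, s.
#' @param nIter number of surrogates.
#' @param seed integer seed.
#' @param nBins number of phase bins.
#' @return The [phaseLocking()] list extended with \code{null} (surrogate
#'   r values), \code{threshold} (95th percentile) and \code{is_locked}.
#' @export
jitterTest <- function(spikes, phaseVec, frameRate = 80, jitter = 0.15,
                       nIter = 1000, seed = 1, nBins = 24) {
  if (is(spikes, "SpikeTrain")) spikes <- spikeTimes(spikes)
  actual <- phaseLocking(spikes, phaseVec, frameRate, nBins)
  if (!is.finite(actual$r))
    return(c(actual, list(null = rep(NA_real_, nIter), threshold = NA_real_,
                          is_locked = FALSE)))
  width <- 360 / nBins
  centers <- (seq_len(nBins) - 0.5) * width
  occ <- actual$occupancy
  n <- length(spikes)
  set.seed(deriveSeed(seed, "jitter"))
  rNull <- numeric(nIter)
  chunk <- max(1L, min(nIter, floor(2e6 / max(n, 1))))
  done <- 0L
  expTheta <- exp(1i * centers * pi / 180)
  invOcc <- ifelse(occ > 0, 1 / occ, 0)
  while (done < nIter) {
    m <- min(chunk, nIter - done)
    jit <- matrix(stats::runif(n * m, -jitter, jitter), nrow = n)
    bins <- spikePhaseBins(rep(spikes, m) + as.numeric(jit),
                           phaseVec, frameRate, nBins)
    iter <- rep(seq_len(m), each = n)
    ok <- !is.na(bins)
    counts <- matrix(tabulate(bins[ok] + nBins * (iter[ok] - 1L),
                              nbins = nBins * m), nrow = nBins)
    w <- counts * invOcc
    s <- colSums(w)
    z <- as.vector(expTheta %*% w)
    rNull[done + seq_len(m)] <- ifelse(s > 0, Mod(z) / s, NA)
    done <- done + m
  }
  thr <- stats::quantile(rNull, 0.95, na.rm = TRUE, names = FALSE)
  c(actual, list(null = rNull, threshold = thr,
                 is_locked = isTRUE(actual$r > thr)))
}

#' Per-unit statistics table for one segmented session
#'
#' Runs speed tuning and, for each limb, phase locking with the jitter
#' null, for every unit of a session. A unit is phase locked overall when
#' locked to at least one limb's phase.
#'
#' @param session a \linkS4class{GaitSession}.
#' @param seg segmentation from [segmentSession()].
#' @param config configuration list (see [defaultConfig()]).
#' @param seed integer seed for the jitter surrogates.
#' @param jitterIterations surrogate count (defaults from config).
#' @return data.frame with one row per unit: \code{unit_id}, \code{region},
#'   \code{R2}, \code{speed_p}, \code{speed_excluded}, per-limb \code{r_*}
#'   and \code{preferred_phase_*}, per-limb \code{locked_*} and
#'   \code{locked_any}.
#' @export
unitStats <- function(session, seg, config = defaultConfig(), seed = 1,
                      jitterIterations = config$jitter_iterations) {
  fps <- frameRate(session)
  walking <- logical(length(seg$speed))
  for (b in seq_len(nrow(seg$bouts)))
    walking[(seg$bouts$onset_frame[b] + 1L):(seg$bouts$offset_frame[b] + 1L)] <- TRUE

  rows <- lapply(units(session), function(u) {
    st <- speedTuning(u, seg$speed, walking, fps,
                      binWidth = config$speed_bin_width,
                      binMin = config$speed_bin_min,
                      binMax = config$speed_bin_max)
    row <- data.frame(unit_id = unitId(u), region = region(u),
                      R2 = st$r_squared, speed_p = st$p_value,
                      speed_excluded = st$excluded)
    lockedAny <- FALSE
    for (limb in LIMBS) {
      jt <- jitterTest(u, seg$phase[[limb]], fps,
                       jitter = config$jitter_s, nIter = jitterIterations,
                       seed = deriveSeed(seed, paste0(unitId(u), "/", limb)),
                       nBins = config$phase_hist_bins)
      row[[paste0("r_", limb)]] <- jt$r
      row[[paste0("preferred_phase_", limb)]] <- jt$preferred_phase
      row[[paste0("locked_", limb)]] <- jt$is_locked
      lockedAny <- lockedAny || jt$is_locked
    }
    row$locked_any <- lockedAny
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
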