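#' Savitzky-Golay smoothing of tracked coordinates
#'
#' Replaces every coordinate channel by its local third-order polynomial
#' fit (7-frame window by default, 87.5 ms at 80 fps — short enough to
#' preserve the 8 Hz upper edge of the gait band). Polynomials up to the
#' filter order are reproduced exactly, including at the edges.
#'
#' @param session a \linkS4class{GaitSession}.
#' @param window odd window length in frames (>= \code{polyorder + 2}).
#' @param polyorder polynomial order.
#' @return The session with smoothed kinematics.
#' @export
smoothPositions <- function(session, window = 7, polyorder = 3) {
  stopifnot(is(session, "GaitSession"))
  if (window < polyorder + 2)
    stop("window must be at least polyorder + 2 frames")
  if (window %% 2 == 0) stop("window must be odd")
  kin <- kinematics(session)
  for (col in setdiff(KIN_COLUMNS, "frame"))
    kin[[col]] <- signal::sgolayfilt(kin[[col]], p = polyorder, n = window)
  session@kinematics <- kin
  session
}

#' Whole-body speed from limb speeds
#'
#' Per-limb speed is the frame-to-frame displacement times the frame rate;
#' body speed is the root-mean-square of the four limb speeds. The first
#' frame duplicates the second (no preceding displacement).
#'
#' @param session a \linkS4class{GaitSession} (smooth first for analysis).
#' @return Numeric vector of body speed (mm/s), one value per frame.
#' @export
bodySpeed <- function(session) {
  kin <- kinematics(session)
  fps <- frameRate(session)
  sq <- 0
  for (limb in c("lf", "rf", "lr", "rr")) {
    vx <- diff(kin[[paste0(limb, "_x")]])
    vy <- diff(kin[[paste0(limb, "_y")]])
    sq <- sq + (vx^2 + vy^2) * fps^2
  }
  v <- sqrt(sq / 4)
  c(v[1L], v)
}

#' Detect walking bouts from body speed
#'
#' Candidate bouts are periods in which body speed exceeds
#' \code{speed_threshold} continuously for at least \code{speed_sustain}
#' seconds. Each candidate onset is refined to the peak of body
#' acceleration (centred difference of body speed) within a
#' \code{onset_search_frames}-frame window centred on the threshold
#' crossing; candidates whose largest acceleration peak has topographic
#' prominence at or below \code{accel_prominence} (mm/s^2) are discarded.
#' The bout ends when speed stays below the threshold for
#' \code{offset_below} seconds. Bouts shorter than
#' \code{min_bout_duration} are dropped, and of any two bouts closer than
#' \code{min_bout_gap} seconds the later one is dropped.
#'
#' @param speed per-frame body speed, mm/s (from [bodySpeed()]).
#' @param frameRate frames per second.
#' @param speed_threshold candidate threshold, mm/s.
#' @param speed_sustain minimum supra-threshold duration, s.
#' @param onset_search_frames total width of the acceleration-peak search
#'   window, frames.
#' @param accel_prominence minimum peak prominence, mm/s^2 (exclusive).
#' @param min_bout_duration minimum accepted bout length, s.
#' @param min_bout_gap minimum separation between accepted bouts, s.
#' @param offset_below sub-threshold time defining the bout offset, s.
#' @return data.frame with 0-based \code{onset_frame}, \code{offset_frame}
#'   and \code{peak_prominence} (mm/s^2); zero rows when nothing qualifies.
#' @export
detectBouts <- function(speed, frameRate = 80, speed_threshold = 50,
                        speed_sustain = 0.5, onset_search_frames = 50,
                        accel_prominence = 1000, min_bout_duration = 1,
                        min_bout_gap = 1, offset_below = 0.25) {
  n <- length(speed)
  empty <- data.frame(onset_frame = integer(0), offset_frame = integer(0),
                      peak_prominence = numeric(0))
  if (n < 3L) return(empty)
  accel <- c(0, (speed[3:n] - speed[1:(n - 2)]) * frameRate / 2, 0)

  fast <- speed >= speed_threshold
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  minRun <- ceiling(speed_sustain * frameRate)
  cand <- starts[r$values & r$lengths >= minRun]
  if (!length(cand)) return(empty)

  half <- floor(onset_search_frames / 2)
  offRun <- max(1L, ceiling(offset_below * frameRate))
  bouts <- empty
  for (c0 in cand) {
    wlo <- max(1L, c0 - half); whi <- min(n, c0 + half)
    seg <- accel[wlo:whi]
    peaks <- localMaxima(seg)
    if (!length(peaks)) next
    prom <- vapply(peaks, function(i) peakProminence(seg, i), numeric(1))
    keep <- prom > accel_prominence
    if (!any(keep)) next
    peaks <- peaks[keep]; prom <- prom[keep]
    best <- peaks[which.max(seg[peaks])]
    onset <- wlo + best - 1L

    # offset: last fast frame before speed stays sub-threshold offRun frames
    offset <- n
    slow <- !fast
    i <- max(onset + 1L, c0)
    while (i <= n - offRun + 1L) {
      if (all(slow[i:(i + offRun - 1L)])) { offset <- i - 1L; break }
      i <- i + 1L
    }
    if (offset <= onset) next
    bouts <- rbind(bouts, data.frame(onset_frame = onset - 1L,
                                     offset_frame = offset - 1L,
                                     peak_prominence = prom[which.max(seg[peaks])]))
  }
  if (!nrow(bouts)) return(empty)
  bouts <- unique(bouts[order(bouts$onset_frame), ])
  bouts <- bouts[(bouts$offset_frame - bouts$onset_frame + 1) / frameRate >=
                   min_bout_duration, , drop = FALSE]
  if (!nrow(bouts)) return(empty)

  # of any pair closer than min_bout_gap, keep the earlier
  keep <- logical(nrow(bouts))
  lastOffset <- -Inf
  for (i in seq_len(nrow(bouts))) {
    gap <- (bouts$onset_frame[i] - lastOffset) / frameRate
    if (gap >= min_bout_gap) { keep[i] <- TRUE; lastOffset <- bouts$offset_frame[i] }
  }
  rownames(bouts) <- NULL
  bouts[keep, , drop = FALSE]
}

#' Project a limb onto the nose-tail axis
#'
#' Returns the signed distance of the limb from the nose along the
#' nose-to-tail direction (mm): small values mean the limb is close to the
#' nose, so gait-cycle minima mark stance onsets.
#'
#' @param session a \linkS4class{GaitSession}.
#' @param limb one of \code{"LF"}, \code{"RF"}, \code{"LR"}, \code{"RR"}.
#' @return Numeric vector, one value per frame.
#' @export
projectLimb <- function(session, limb) {
  stopifnot(limb %in% LIMBS)
  kin <- kinematics(session)
  ax <- kin$tail_x - kin$nose_x
  ay <- kin$tail_y - kin$nose_y
  len <- sqrt(ax^2 + ay^2)
  lx <- tolower(substr(limb, 1, 2))
  ((kin[[paste0(lx, "_x")]] - kin$nose_x) * ax +
   (kin[[paste0(lx, "_y")]] - kin$nose_y) * ay) / len
}

#' Band-pass filter a projected limb signal to the gait band
#'
#' Second-order Butterworth band-pass (0.5-8 Hz by default) applied
#' forward and backward for zero phase distortion, removing both the slow
#' whole-body translation and super-gait noise.
#'
#' @param x projected limb signal (mm), one segment.
#' @param frameRate sampling rate, Hz.
#' @param low,high band edges, Hz.
#' @return Filtered signal of the same length.
#' @export
bandpassGait <- function(x, frameRate = 80, low = 0.5, high = 8) {
  bf <- signal::butter(2, c(low, high) / (frameRate / 2), type = "pass")
  if (length(x) < 3 * max(length(bf$b), length(bf$a)))
    stop("segment too short to band-pass (need at least 3 filter lengths)")
  as.numeric(signal::filtfilt(bf, x - mean(x)))  # de-mean tames edge transients
}

# Alternating extrema of a filtered gait signal. Consecutive minima keep
# the deeper one, consecutive maxima the higher, so minima and maxima
# strictly alternate on return.
alternatingExtrema <- function(x) {
  mins <- localMinima(x)
  maxs <- localMaxima(x)
  if (!length(mins) || !length(maxs))
    return(list(minima = integer(0), maxima = integer(0)))
  ev <- rbind(data.frame(i = mins, type = "min"),
              data.frame(i = maxs, type = "max"))
  ev <- ev[order(ev$i), ]
  keep <- ev[1, ]
  for (k in seq_len(nrow(ev))[-1]) {
    last <- nrow(keep)
    if (ev$type[k] == keep$type[last]) {
      better <- if (ev$type[k] == "min") x[ev$i[k]] < x[keep$i[last]]
                else x[ev$i[k]] > x[keep$i[last]]
      if (better) keep[last, ] <- ev[k, ]
    } else keep <- rbind(keep, ev[k, ])
  }
  list(minima = keep$i[keep$type == "min"], maxima = keep$i[keep$type == "max"])
}

#' Segment strides within one walking bout
#'
#' Stance onsets are the local minima of the band-passed projected limb
#' signal (limb closest to the nose), swing onsets the local maxima; one
#' stride runs from a stance onset through its swing onset to the next
#' stance onset. Partial cycles at the bout edges are dropped.
#'
#' @param filtered band-passed projected signal covering one bout.
#' @param onsetFrame 0-based session frame of the first sample of
#'   \code{filtered} (used to report absolute frames).
#' @param limb limb label stored in the result.
#' @param frameRate frames per second.
#' @return data.frame with \code{limb}, 0-based \code{stance_onset_frame},
#'   \code{swing_onset_frame}, \code{end_frame} and \code{duration_s};
#'   zero rows if no full cycle is found.
#' @export
segmentStrides <- function(filtered, onsetFrame = 0L, limb = "LF",
                           frameRate = 80) {
  ext <- alternatingExtrema(filtered)
  empty <- data.frame(limb = character(0), stance_onset_frame = integer(0),
                      swing_onset_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0))
  mins <- ext$minima
  if (length(mins) < 2L) return(empty)
  out <- empty
  for (k in seq_len(length(mins) - 1L)) {
    sw <- ext$maxima[ext$maxima > mins[k] & ext$maxima < mins[k + 1L]]
    if (length(sw) != 1L) next
    out <- rbind(out, data.frame(
      limb = limb,
      stance_onset_frame = onsetFrame + mins[k] - 1L,
      swing_onset_frame = onsetFrame + sw - 1L,
      end_frame = onsetFrame + mins[k + 1L] - 1L,
      duration_s = (mins[k + 1L] - mins[k]) / frameRate))
  }
  rownames(out) <- NULL
  out
}

#' Instantaneous gait phase of one limb over one bout
#'
#' The phase is the argument of the analytic signal of the band-passed
#' projected limb signal, shifted by +180 degrees so that signal minima
#' (stance onsets) sit at 0 degrees, wrapped to [0, 360).
#'
#' @param filtered band-passed projected signal covering one bout.
#' @return Numeric vector of phase in degrees, one value per sample.
#' @export
limbPhase <- function(filtered) {
  if (stats::sd(filtered) < 1e-9)
    stop("phase undefined: filtered signal is constant")
  a <- analyticSignal(filtered)
  wrapDeg(Arg(a) * 180 / pi + 180)
}

#' Segment a session into bouts, strides and phase series
#'
#' End-to-end kinematic processing: Savitzky-Golay smoothing, body speed,
#' bout detection, then per bout and per limb the band-passed projection,
#' stride segmentation and instantaneous phase.
#'
#' @param session a \linkS4class{GaitSession}.
#' @param config configuration list (see [defaultConfig()]).
#' @return list with \code{bouts} (data.frame), \code{strides} (data.frame
#'   over all limbs and bouts), \code{phase} (data.frame \code{frame},
#'   \code{LF}, \code{RF}, \code{LR}, \code{RR}; degrees, NA outside
#'   bouts), \code{speed} (per-frame body speed) and the smoothed session.
#' @export
segmentSession <- function(session, config = defaultConfig()) {
  smoothed <- smoothPositions(session, config$sg_window, config$sg_order)
  speed <- bodySpeed(smoothed)
  fps <- frameRate(session)
  bouts <- detectBouts(speed, fps,
                       speed_threshold = config$speed_threshold,
                       speed_sustain = config$speed_sustain,
                       onset_search_frames = config$onset_search_frames,
                       accel_prominence = config$accel_prominence,
                       min_bout_duration = config$min_bout_duration,
                       min_bout_gap = config$min_bout_gap,
                       offset_below = config$offset_below)
  nFrames <- nrow(kinematics(session))
  phase <- data.frame(frame = kinematics(session)$frame)
  for (limb in LIMBS) phase[[limb]] <- NA_real_
  strides <- NULL
  for (limb in LIMBS) {
    proj <- projectLimb(smoothed, limb)
    for (b in seq_len(nrow(bouts))) {
      i0 <- bouts$onset_frame[b] + 1L
      i1 <- bouts$offset_frame[b] + 1L
      filt <- tryCatch(bandpassGait(proj[i0:i1], fps, config$band_low,
                                    config$band_high),
                       error = function(e) NULL)
      if (is.null(filt)) next
      st <- segmentStrides(filt, onsetFrame = bouts$onset_frame[b],
                           limb = limb, frameRate = fps)
      strides <- rbind(strides, st)
      ph <- tryCatch(limbPhase(filt), error = function(e) NULL)
      if (!is.null(ph)) phase[[limb]][i0:i1] <- ph
    }
  }
  if (is.null(strides))
    strides <- data.frame(limb = character(0), stance_onset_frame = integer(0),
                          swing_onset_frame = integer(0),
                          end_frame = integer(0), duration_s = numeric(0))
  list(bouts = bouts, strides = strides, phase = phase, speed = speed,
       session = smoothed)
}
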