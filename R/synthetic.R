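#' Gait parameters for the synthetic-session generator
#'
#' Defaults describe mouse overground walking as seen by an 80 fps
#' bottom-up camera: 2.5 Hz strides, 15 mm limb excursion, a trot-like
#' inter-limb pattern (diagonal pairs in phase: LR = RF = 0 deg,
#' LF = RR = 180 deg), bouts of a few seconds separated by rests, and body
#' speeds spanning 50-310 mm/s.
#'
#' @param stride_frequency stride rate, Hz (must lie in 0.5-8 Hz, the gait
#'   band used downstream).
#' @param stride_amplitude peak-to-peak limb excursion along the body axis, mm.
#' @param phase_offsets named degrees per limb relative to LR
#'   (names LF, RF, LR, RR), each in [0, 360).
#' @param bout_duration mean bout length, s (minimum 1 s).
#' @param bout_gap mean rest between bouts, s (minimum 1 s).
#' @param speed_range commanded body-speed range during bouts, mm/s.
#' @param frame_rate video frame rate, Hz.
#' @param phase_jitter_sd per-frame jitter of the phase increment, degrees.
#' @param noise_sd tracking-noise amplitude, mm (temporally correlated).
#' @return Named list of validated gait parameters.
#' @export
gaitParams <- function(stride_frequency = 2.5, stride_amplitude = 15,
                       phase_offsets = c(LF = 180, RF = 0, LR = 0, RR = 180),
                       bout_duration = 3, bout_gap = 2.5,
                       speed_range = c(50, 310), frame_rate = 80,
                       phase_jitter_sd = 3, noise_sd = 0.5) {
  if (stride_frequency < 0.5 || stride_frequency > 8)
    stop("stride_frequency must lie within 0.5-8 Hz")
  if (bout_duration < 1) stop("bout_duration must be >= 1 s")
  if (bout_gap < 1) stop("bout_gap must be >= 1 s")
  stopifnot(all(LIMBS %in% names(phase_offsets)),
            all(phase_offsets >= 0 & phase_offsets < 360),
            length(speed_range) == 2L, speed_range[1] < speed_range[2])
  list(stride_frequency = stride_frequency,
       stride_amplitude = stride_amplitude,
       phase_offsets = phase_offsets[LIMBS],
       bout_duration = bout_duration, bout_gap = bout_gap,
       speed_range = speed_range, frame_rate = frame_rate,
       phase_jitter_sd = phase_jitter_sd, noise_sd = noise_sd)
}

#' Firing-rate tuning profile of a synthetic unit
#'
#' Parameters of the log-linear intensity model used by [generateSpikes()]:
#' a baseline rate, an onset-locked ramp (linear rise over \code{ramp_lead}
#' seconds to a peak 0.1 s after bout onset, then exponential decay with
#' time constant \code{ramp_decay}), a log-linear body-speed gain, and von
#' Mises gait-phase tuning of concentration \code{phase_kappa} about
#' \code{preferred_phase} of \code{preferred_limb}.
#'
#' @param baseline_rate baseline firing rate, Hz (> 0).
#' @param ramp_amplitude peak rate increase at the ramp peak, Hz (>= 0).
#' @param ramp_lead ramp rise time before onset, s.
#' @param ramp_decay post-peak exponential decay constant, s.
#' @param speed_gain log-rate gain per mm/s of commanded body speed.
#' @param phase_kappa von Mises concentration (>= 0).
#' @param preferred_phase preferred gait phase, degrees.
#' @param preferred_limb one of LF, RF, LR, RR.
#' @return Named list of validated tuning parameters.
#' @export
tuningProfile <- function(baseline_rate = 8, ramp_amplitude = 0,
                          ramp_lead = 0.5, ramp_decay = 0.3,
                          speed_gain = 0, phase_kappa = 0,
                          preferred_phase = 0, preferred_limb = "LR") {
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (phase_kappa < 0) stop("phase_kappa must be >= 0")
  if (ramp_amplitude < 0) stop("ramp_amplitude must be >= 0")
  stopifnot(preferred_limb %in% LIMBS, ramp_lead > 0, ramp_decay > 0)
  list(baseline_rate = baseline_rate, ramp_amplitude = ramp_amplitude,
       ramp_lead = ramp_lead, ramp_decay = ramp_decay,
       speed_gain = speed_gain, phase_kappa = phase_kappa,
       preferred_phase = wrapDeg(preferred_phase),
       preferred_limb = preferred_limb)
}

# Asymmetric stride waveform: limb displacement along the direction of
# travel as a function of gait phase (radians). At phase 0 (stance onset)
# the limb is fully protracted, i.e. nearest the nose, so the projected
# limb-to-nose distance is minimal; the warp makes swing faster than stance.
strideWave <- function(phaseRad, asym = 0.4) {
  cos(phaseRad - asym * sin(phaseRad))
}

#' Generate synthetic walking kinematics with ground truth
#'
#' Simulates per-frame coordinates of the six tracked features over
#' \code{duration} seconds: alternating rest periods and walking bouts in
#' which the nose-tail axis translates at a smoothly varying commanded
#' speed inside \code{gait$speed_range} while each limb oscillates along
#' the body axis at the stride frequency with the configured trot offsets.
#' Each bout starts with a sharp acceleration transient (so bouts survive
#' the downstream 1000 mm/s^2 prominence filter) and tracking noise is
#' temporally correlated with marginal sd \code{gait$noise_sd}.
#'
#' @param gait a [gaitParams()] list.
#' @param duration session length, s; must accommodate at least one bout
#'   with its surrounding rests.
#' @param seed integer seed.
#' @return A \linkS4class{GaitSession} with no units and ground truth
#'   components \code{bouts} (onset/offset frames, 0-based),
#'   \code{phase} (per-frame per-limb phase, degrees, NA at rest) and
#'   \code{speed} (per-frame commanded body speed, mm/s).
#' @export
generateKinematics <- function(gait = gaitParams(), duration = 300, seed = 1) {
  fps <- gait$frame_rate
  dt <- 1 / fps
  nFrames <- floor(duration * fps)
  if (duration < gait$bout_duration + 2 * gait$bout_gap)
    stop("duration too short for one bout with surrounding rests")
  set.seed(deriveSeed(seed, "kinematics"))

  # ---- bout schedule: alternating rest / walk, jittered around the means
  walking <- logical(nFrames)
  vCmd <- numeric(nFrames)           # commanded body speed, mm/s
  onsetFr <- integer(0); offsetFr <- integer(0)
  t <- gait$bout_gap * stats::runif(1, 0.8, 1.2)
  while (TRUE) {
    len <- max(1.2, gait$bout_duration * stats::runif(1, 0.7, 1.4))
    f0 <- floor(t * fps) + 1L
    f1 <- min(floor((t + len) * fps), nFrames)
    if (f0 + fps < f1 && t + len + 1 < duration) {
      walking[f0:f1] <- TRUE
      onsetFr <- c(onsetFr, f0); offsetFr <- c(offsetFr, f1)
    } else break
    t <- t + len + max(1.2, gait$bout_gap * stats::runif(1, 0.7, 1.4))
    if (t >= duration - 1) break
  }
  if (!length(onsetFr)) stop("duration too short for one bout with surrounding rests")

  # ---- commanded speed: sharp onset transient, then a noisy relaxation
  # toward a per-bout cruise speed drawn from the full range
  lo <- gait$speed_range[1]; hi <- gait$speed_range[2]
  for (b in seq_along(onsetFr)) {
    f0 <- onsetFr[b]; f1 <- offsetFr[b]
    n <- f1 - f0 + 1L
    cruise <- stats::runif(1, lo + 10, hi - 20)
    start <- max(150, cruise)       # onset burst clears the prominence gate
    v <- numeric(n); v[1] <- start
    eps <- stats::rnorm(n, 0, 6)
    for (i in 2:n)
      v[i] <- min(hi, max(lo, v[i - 1] + 0.08 * (cruise - v[i - 1]) + eps[i]))
    v <- gaussSmooth(v, 1, 4)                       # ~50 ms smoothing
    v <- pmin(hi, pmax(lo, v))
    ramp <- 2L                                      # onset transient, frames
    if (n > ramp) v[1:ramp] <- v[ramp + 1] * seq_len(ramp) / (ramp + 1)
    vCmd[f0:f1] <- v
  }

  # ---- gait phase per limb: common oscillator + fixed offsets + jitter
  phi <- rep(NA_real_, nFrames)                     # LR reference phase, deg
  for (b in seq_along(onsetFr)) {
    idx <- onsetFr[b]:offsetFr[b]
    inc <- 360 * gait$stride_frequency * dt *
      (0.6 + 0.4 * vCmd[idx] / mean(vCmd[idx]))   # sub-linear speed coupling
    inc <- inc + stats::rnorm(length(idx), 0, gait$phase_jitter_sd)
    phi[idx] <- wrapDeg(cumsum(inc) - inc[1])
  }
  phase <- sapply(gait$phase_offsets, function(off) wrapDeg(phi + off))
  colnames(phase) <- LIMBS

  # ---- positions: body axis along +x, heading fixed, arena-free
  bodyX <- cumsum(ifelse(walking, vCmd, 0)) * dt
  bodyLen <- 70                                     # nose-to-tail, mm
  hipOff <- c(LF = 25, RF = 25, LR = -20, RR = -20) # along body axis
  latOff <- c(LF = 12, RF = -12, LR = 12, RR = -12) # lateral, mm

  corrNoise <- function(n, sd) {                    # AR(1), ~0.06 s memory
    rho <- 0.95
    e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
    as.numeric(stats::filter(e, rho, method = "recursive"))
  }
  # stride length grows with speed: slow gait has shorter limb excursions
  ampFac <- pmin(1.3, pmax(0.25, ifelse(walking, vCmd, 180) / 180))
  amp <- gait$stride_amplitude / 2 * gaussSmooth(ampFac, 1, 4)
  kin <- data.frame(frame = 0:(nFrames - 1L))
  kin$nose_x <- bodyX + bodyLen / 2 + corrNoise(nFrames, gait$noise_sd)
  kin$nose_y <- corrNoise(nFrames, gait$noise_sd)
  kin$tail_x <- bodyX - bodyLen / 2 + corrNoise(nFrames, gait$noise_sd)
  kin$tail_y <- corrNoise(nFrames, gait$noise_sd)
  for (limb in LIMBS) {
    osc <- ifelse(is.na(phase[, limb]), 1,
                  strideWave(phase[, limb] * pi / 180)) * amp
    lx <- tolower(substr(limb, 1, 2))
    kin[[paste0(lx, "_x")]] <- bodyX + hipOff[limb] + osc +
      corrNoise(nFrames, gait$noise_sd)
    kin[[paste0(lx, "_y")]] <- latOff[limb] + corrNoise(nFrames, gait$noise_sd)
  }

  # truth onset is the first walking frame; the commanded acceleration
  # transient peaks within ~1 frame of it
  gt <- list(
    bouts = data.frame(onset_frame = onsetFr - 1L, offset_frame = offsetFr - 1L),
    phase = data.frame(frame = 0:(nFrames - 1L), phase),
    speed = data.frame(frame = 0:(nFrames - 1L), speed = vCmd))
  GaitSession(sprintf("synthetic-%d", seed), kin, list(),
              frameRate = fps, duration = nFrames / fps, groundTruth = gt)
}

# Onset-locked ramp shape in [0, 1]: linear rise from (onset - lead) to the
# peak at (onset + 0.1 s), exponential decay afterwards; max over bouts.
rampShape <- function(tGrid, onsets, lead, decay) {
  shape <- numeric(length(tGrid))
  peakLag <- 0.1
  for (t0 in onsets) {
    d <- tGrid - t0
    s <- ifelse(d < -lead, 0,
         ifelse(d <= peakLag, (d + lead) / (lead + peakLag),
                exp(-(d - peakLag) / decay)))
    shape <- pmax(shape, s)
  }
  shape
}

#' Generate an inhomogeneous-Poisson spike train for one unit
#'
#' The intensity follows a log-link model on a 1 ms grid:
#' \deqn{\log\lambda(t) = \log b + s(t)\,\log(1 + A/b) + g\,v(t) +
#'   \kappa\,\cos(\theta(t) - \theta_0)}
#' with baseline \eqn{b}, ramp shape \eqn{s(t)} (see [tuningProfile()]) and
#' amplitude \eqn{A} Hz, log-linear speed gain \eqn{g}, and von Mises phase
#' tuning of concentration \eqn{\kappa} about \eqn{\theta_0} on the
#' preferred limb's gait phase. Speed and phase terms act only during
#' walking. Spikes are drawn by thinning a homogeneous process at the grid
#' maximum, so the realised intensity is exact.
#'
#' @param session a \linkS4class{GaitSession} from [generateKinematics()]
#'   (ground truth required).
#' @param profile a [tuningProfile()].
#' @param seed integer seed.
#' @param unitId identifier for the returned unit.
#' @param region region label for the returned unit.
#' @return A \linkS4class{SpikeTrain}.
#' @export
generateSpikes <- function(session, profile, seed = 1, unitId = "u1",
                           region = "M1") {
  gt <- groundTruth(session)
  if (is.null(gt$phase) || is.null(gt$speed) || is.null(gt$bouts))
    stop("session carries no generator ground truth")
  if (profile$phase_kappa < 0) stop("phase_kappa must be >= 0")
  fps <- frameRate(session)
  dur <- duration(session)
  grid <- 0.001
  tGrid <- seq(0, dur - grid, by = grid)
  frameOf <- pmin(nrow(kinematics(session)), floor(tGrid * fps) + 1L)

  speed <- gt$speed$speed[frameOf]
  theta <- gt$phase[[profile$preferred_limb]][frameOf]
  walking <- !is.na(theta)

  logLam <- rep(log(profile$baseline_rate), length(tGrid))
  if (profile$ramp_amplitude > 0) {
    onsets <- (gt$bouts$onset_frame + 1) / fps
    logLam <- logLam + rampShape(tGrid, onsets, profile$ramp_lead,
                                 profile$ramp_decay) *
      log1p(profile$ramp_amplitude / profile$baseline_rate)
  }
  if (profile$speed_gain != 0)
    logLam <- logLam + profile$speed_gain * ifelse(walking, speed, 0)
  if (profile$phase_kappa > 0)
    logLam <- logLam + profile$phase_kappa *
      ifelse(walking, cos((theta - profile$preferred_phase) * pi / 180), 0)
  lam <- exp(logLam)

  set.seed(deriveSeed(seed, paste0("spikes/", unitId)))
  lamMax <- max(lam)
  n <- stats::rpois(1, lamMax * dur)
  cand <- sort(stats::runif(n, 0, dur))
  idx <- pmin(length(lam), floor(cand / grid) + 1L)
  keep <- stats::runif(n) < lam[idx] / lamMax
  SpikeTrain(unitId, cand[keep], region)
}

#' Cohort specification for [generateCohort()]
#'
#' @param regions named list (names from M1, mPFC, DMS, DLS) of region
#'   profiles, each a list with \code{n_units} and, per tuning parameter,
#'   a \code{c(mean, sd)} pair from which unit profiles are drawn
#'   (truncated at the parameter's validity bound); see [regionProfile()].
#' @param n_sessions sessions per region.
#' @param duration session length, s.
#' @param gait a [gaitParams()] list shared by all sessions.
#' @param seed master seed.
#' @return Named list describing the cohort.
#' @export
cohortSpec <- function(regions, n_sessions = 1, duration = 300,
                       gait = gaitParams(), seed = 1) {
  stopifnot(length(regions) >= 1, !is.null(names(regions)),
            all(names(regions) %in% REGIONS))
  for (r in regions) if (is.null(r$n_units) || r$n_units < 1)
    stop("every region profile needs n_units >= 1")
  list(regions = regions, n_sessions = n_sessions, duration = duration,
       gait = gait, seed = seed)
}

#' Distribution over tuning profiles for one region
#'
#' Each parameter is a \code{c(mean, sd)} pair; unit-level values are drawn
#' normally and truncated to the parameter's valid range (rates > 0.1 Hz,
#' kappa >= 0). Preferred phases are uniform on the circle and preferred
#' limbs uniform over the four limbs.
#'
#' @param n_units units to draw for this region.
#' @param baseline_rate,ramp_amplitude,speed_gain,phase_kappa c(mean, sd).
#' @param ramp_lead,ramp_decay c(mean, sd), seconds.
#' @return List consumed by [cohortSpec()].
#' @export
regionProfile <- function(n_units, baseline_rate = c(8, 2),
                          ramp_amplitude = c(0, 0), speed_gain = c(0, 0),
                          phase_kappa = c(0, 0), ramp_lead = c(0.5, 0.1),
                          ramp_decay = c(0.3, 0.05)) {
  list(n_units = as.integer(n_units), baseline_rate = baseline_rate,
       ramp_amplitude = ramp_amplitude, speed_gain = speed_gain,
       phase_kappa = phase_kappa, ramp_lead = ramp_lead,
       ramp_decay = ramp_decay)
}

#' Generate a cohort of synthetic sessions
#'
#' One set of sessions per region; each session gets fresh kinematics and
#' \code{n_units / n_sessions} units drawn from the region's profile
#' distribution. Unit-level ground-truth profiles are stored in the
#' session's \code{groundTruth$profiles} table (written as
#' \code{ground_truth.tsv} by [writeSession()]).
#'
#' @param spec a [cohortSpec()].
#' @return List of \linkS4class{GaitSession} objects.
#' @export
generateCohort <- function(spec) {
  sessions <- list()
  drawPar <- function(ms, lo = -Inf) max(lo, stats::rnorm(1, ms[1], ms[2]))
  for (regionName in names(spec$regions)) {
    rp <- spec$regions[[regionName]]
    perSession <- ceiling(rp$n_units / spec$n_sessions)
    made <- 0L
    for (s in seq_len(spec$n_sessions)) {
      kinSeed <- deriveSeed(spec$seed, paste0("cohort/", regionName, "/", s))
      ses <- generateKinematics(spec$gait, spec$duration, seed = kinSeed)
      ses@sessionId <- sprintf("%s-s%02d", regionName, s)
      nHere <- min(perSession, rp$n_units - made)
      set.seed(deriveSeed(kinSeed, "profiles"))
      profs <- lapply(seq_len(nHere), function(i) {
        tuningProfile(
          baseline_rate = drawPar(rp$baseline_rate, 0.1),
          ramp_amplitude = drawPar(rp$ramp_amplitude, 0),
          ramp_lead = drawPar(rp$ramp_lead, 0.1),
          ramp_decay = drawPar(rp$ramp_decay, 0.05),
          speed_gain = stats::rnorm(1, rp$speed_gain[1], rp$speed_gain[2]),
          phase_kappa = drawPar(rp$phase_kappa, 0),
          preferred_phase = stats::runif(1, 0, 360),
          preferred_limb = sample(LIMBS, 1))
      })
      ids <- sprintf("%s-u%03d", ses@sessionId, seq_len(nHere))
      ses@units <- lapply(seq_len(nHere), function(i)
        generateSpikes(ses, profs[[i]], seed = kinSeed, unitId = ids[i],
                       region = regionName))
      ses@groundTruth$profiles <- data.frame(
        unit_id = ids,
        region = regionName,
        baseline_rate = vapply(profs, `[[`, numeric(1), "baseline_rate"),
        ramp_amplitude = vapply(profs, `[[`, numeric(1), "ramp_amplitude"),
        speed_gain = vapply(profs, `[[`, numeric(1), "speed_gain"),
        phase_kappa = vapply(profs, `[[`, numeric(1), "phase_kappa"),
        preferred_phase = vapply(profs, `[[`, numeric(1), "preferred_phase"),
        preferred_limb = vapply(profs, `[[`, character(1), "preferred_limb"))
      made <- made + nHere
      validObject(ses)
      sessions[[ses@sessionId]] <- ses
    }
  }
  sessions
}

#' Preset region profiles for the two canonical tuning families
#'
#' Two calibration presets for contrast experiments: \code{"DMS-like"}
#' units carry strong, early preparatory ramps (large \code{ramp_amplitude},
#' \code{ramp_lead} around 0.8 s) with weak gait-phase coupling, whereas
#' \code{"M1-like"} units have weak ramps but strong phase coupling
#' (kappa around 2) and a larger speed gain. The presets are calibration
#' knobs for synthetic experiments, not estimates of any recorded
#' population.
#'
#' @param type \code{"M1-like"} or \code{"DMS-like"}.
#' @param n_units units to draw.
#' @return A [regionProfile()] list.
#' @export
presetProfile <- function(type = c("M1-like", "DMS-like"), n_units = 50) {
  type <- match.arg(type)
  if (type == "M1-like")
    regionProfile(n_units, baseline_rate = c(8, 2),
                  ramp_amplitude = c(2, 1), ramp_lead = c(0.4, 0.1),
                  speed_gain = c(0.004, 0.002), phase_kappa = c(2, 0.4))
  else
    regionProfile(n_units, baseline_rate = c(8, 2),
                  ramp_amplitude = c(15, 4), ramp_lead = c(0.8, 0.15),
                  ramp_decay = c(0.4, 0.1),
                  speed_gain = c(0.001, 0.001), phase_kappa = c(0.3, 0.1))
}
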