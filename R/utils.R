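#' Derive a stage-specific RNG seed from a master seed
#'
#' All randomness in the package flows from one master seed. Each pipeline
#' stage derives its own seed by hashing the stage name together with the
#' master seed, so partial re-runs of a stage reproduce exactly without
#' consuming RNG state from other stages.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. \code{"decode/time"}).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
deriveSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.numeric(master) %% m
  for (c in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 31 + c) %% m
  }
  as.integer(h)
}

#' Analytic signal via the frequency-domain construction
#'
#' Zeroes negative frequencies and doubles positive ones, returning the
#' complex signal whose argument is the instantaneous phase.
#'
#' @param x real numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
analyticSignal <- function(x) {
  n <- length(x)
  if (n < 2L) stop("analytic signal needs at least 2 samples")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Wrap angles in degrees to [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return Wrapped angles.
#' @export
wrapDeg <- function(deg) deg %% 360

#' Signed circular difference a - b in degrees, wrapped to (-180, 180]
#' @param a,b angles in degrees.
#' @return Signed differences.
#' @export
circDiffDeg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Absolute circular difference in degrees, in [0, 180]
#' @param a,b angles in degrees.
#' @return Absolute angular differences.
#' @export
circAbsDiffDeg <- function(a, b) abs(circDiffDeg(a, b))

#' Circular mean of angles in degrees
#' @param deg angles in degrees.
#' @param w optional non-negative weights.
#' @return Mean direction in [0, 360), or NA if the resultant is ~0.
#' @export
circMeanDeg <- function(deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(deg))
  th <- deg * pi / 180
  z <- sum(w * exp(1i * th))
  if (Mod(z) < 1e-12 * max(sum(w), 1)) return(NA_real_)
  wrapDeg(Arg(z) * 180 / pi)
}

#' Rate-weighted circular resultant
#'
#' Returns the mean vector length and direction of weights placed at the
#' given angles: r = |sum(w exp(i theta))| / sum(w).
#'
#' @param deg angles in degrees.
#' @param w non-negative weights (e.g. occupancy-normalised rates).
#' @return list with \code{r} in [0, 1] and \code{mu} in degrees.
#' @export
circResultant <- function(deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(deg))
  stopifnot(length(deg) == length(w), all(w >= 0))
  s <- sum(w)
  if (s <= 0) return(list(r = NA_real_, mu = NA_real_))
  z <- sum(w * exp(1i * deg * pi / 180)) / s
  list(r = Mod(z), mu = wrapDeg(Arg(z) * 180 / pi))
}

# Discrete Gaussian smoothing of a binned sequence. Kernel truncated at
# 4 sd and renormalised to unit sum so total mass is conserved away from
# the vector edges (callers pad the support before cropping).
gaussSmooth <- function(counts, binWidth, kernelSd) {
  half <- max(1L, ceiling(4 * kernelSd / binWidth))
  k <- stats::dnorm(seq(-half, half) * binWidth, sd = kernelSd)
  k <- k / sum(k)
  n <- length(counts)
  padded <- c(numeric(half), counts, numeric(half))
  sm <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(sm[(half + 1):(half + n)])
}

# Topographic prominence of a local maximum at index i of x, computed
# within the vector: height above the higher of the two key saddles.
peakProminence <- function(x, i) {
  n <- length(x)
  h <- x[i]
  # walk left until a sample exceeds h; track the minimum along the way
  lmin <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
  rmin <- h
  j <- i + 1L
  while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
  h - max(lmin, rmin)
}

# Indices of strict-ish local maxima (plateaus take the first sample).
localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  idx[idx > 1L & idx < n]
}

localMinima <- function(x) localMaxima(-x)
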