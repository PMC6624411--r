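# Raw multichannel recordings -> baseline-normalized band-power trials:
# common-average reference, frequency-domain band-pass Hilbert power,
# prestimulus baseline normalization, anti-aliased resampling, reaction-
# time trial selection, and region meta-electrodes (leading principal
# component per region).

#' Band specification with paired sigmoid flanks
#'
#' The band-pass gain is the product of a rising and a falling logistic
#' flank: `g(f) = plogis((f - fLo)/w) * plogis((fHi - f)/w)` with `w` the
#' flank half-width.
#'
#' @param fLo,fHi band edges in Hz.
#' @param flankHalfwidth logistic half-width in Hz (default 1, i.e. 1-Hz
#'   flanks).
#' @return a [BandSpec-class].
#' @export
bandSpec <- function(fLo = 60, fHi = 120, flankHalfwidth = 1) {
  new("BandSpec", fLo = as.numeric(fLo), fHi = as.numeric(fHi),
      flankHalfwidth = as.numeric(flankHalfwidth))
}

.bandGain <- function(f, band) {
  stats::plogis((f - band@fLo) / band@flankHalfwidth) *
    stats::plogis((band@fHi - f) / band@flankHalfwidth)
}

#' Common-average re-referencing
#'
#' Subtracts, at every sample, the mean over the included channels from
#' each included channel; excluded channels pass through unchanged.
#'
#' @param raw a [TrialTensor-class].
#' @param includeMask integer or logical selection of channels to include
#'   (default all).
#' @return the re-referenced [TrialTensor-class].
#' @export
commonAverage <- function(raw, includeMask = NULL) {
  stopifnot(is(raw, "TrialTensor"))
  D <- nChannels(raw)
  idx <- if (is.null(includeMask)) seq_len(D) else seq_len(D)[includeMask]
  if (length(idx) < 2L)
    stop("common-average reference needs at least 2 included channels")
  data <- lapply(raw@data, function(X) {
    avg <- colMeans(X[idx, , drop = FALSE])
    X[idx, ] <- sweep(X[idx, , drop = FALSE], 2L, avg, "-")
    X
  })
  new("TrialTensor", data = data, rate = raw@rate,
      channelLabels = raw@channelLabels, events = raw@events)
}

#' Band power via a frequency-domain band-pass Hilbert filter
#'
#' Per channel, the analytic signal is formed in the frequency domain by
#' zeroing negative frequencies, doubling positive frequencies, and
#' shaping the passband with paired sigmoid flanks; the output is the
#' squared magnitude of the analytic signal (instantaneous band power).
#'
#' @param raw a [TrialTensor-class].
#' @param band a [BandSpec-class]; `fHi` must lie below the Nyquist
#'   frequency.
#' @return a [TrialTensor-class] of nonnegative band power.
#' @export
bandpowerHilbert <- function(raw, band = bandSpec()) {
  stopifnot(is(raw, "TrialTensor"), is(band, "BandSpec"))
  nyq <- samplingRate(raw) / 2
  if (band@fHi >= nyq)
    stop("band upper edge must be below the Nyquist frequency ", nyq, " Hz")
  data <- lapply(raw@data, function(X) {
    n <- ncol(X)
    f <- (seq_len(n) - 1L) / n * samplingRate(raw)
    pos <- f > 0 & f < nyq
    H <- numeric(n)
    H[pos] <- 2 * .bandGain(f[pos], band)
    H[f == 0] <- .bandGain(0, band)
    ny <- which(abs(f - nyq) < 1e-9)
    if (length(ny)) H[ny] <- .bandGain(nyq, band)
    Z <- t(mvfft(t(X)))            # FFT along time, per channel
    Z <- sweep(Z, 2L, H, "*")
    An <- t(mvfft(t(Z), inverse = TRUE)) / n
    Mod(An)^2
  })
  new("TrialTensor", data = data, rate = raw@rate,
      channelLabels = raw@channelLabels, events = raw@events)
}

#' Prestimulus baseline normalization
#'
#' Divides each channel of each trial by its mean power within a window
#' defined relative to that trial's stimulus onset.
#'
#' @param power a [TrialTensor-class] with `stimulus_onset` events.
#' @param window length-2 window in seconds relative to stimulus onset;
#'   default `c(-0.7, -0.2)` (700-200 ms prestimulus).
#' @return the normalized [TrialTensor-class].
#' @export
baselineNormalize <- function(power, window = c(-0.7, -0.2)) {
  stopifnot(is(power, "TrialTensor"))
  stim <- power@events$stimulus_onset
  if (any(is.na(stim))) stop("stimulus_onset required for every trial")
  data <- vector("list", nTrials(power))
  for (i in seq_len(nTrials(power))) {
    X <- power@data[[i]]
    tt <- (seq_len(ncol(X)) - 1L) / power@rate
    sel <- tt >= stim[i] + window[1L] & tt < stim[i] + window[2L]
    if (!any(sel)) stop("baseline window outside trial ", i)
    base <- rowMeans(X[, sel, drop = FALSE])
    if (any(abs(base) < 1e-300))
      stop("degenerate (zero-mean) baseline in trial ", i)
    data[[i]] <- X / base
  }
  new("TrialTensor", data = data, rate = power@rate,
      channelLabels = power@channelLabels, events = power@events)
}

#' Anti-aliased resampling to a lower rate
#'
#' Polyphase anti-aliased resampling of every channel to `targetRate`;
#' event times, being in seconds, are preserved.
#'
#' @param power a [TrialTensor-class].
#' @param targetRate new sampling rate in Hz, at most the current rate
#'   (default 200).
#' @return the resampled [TrialTensor-class].
#' @export
resampleTrials <- function(power, targetRate = 200) {
  stopifnot(is(power, "TrialTensor"))
  rate <- samplingRate(power)
  if (targetRate > rate) stop("upsampling is not supported")
  if (targetRate == rate) return(power)
  frac <- .ratApprox(targetRate / rate)
  p <- frac[1L]; q <- frac[2L]
  data <- lapply(power@data, function(X) {
    out <- t(apply(X, 1L, .resampleChannel, p = p, q = q))
    matrix(out, nrow(X))
  })
  new("TrialTensor", data = data, rate = targetRate,
      channelLabels = power@channelLabels, events = power@events)
}

# Polyphase rational resampling by p/q (p <= q): zero-stuff by p, FIR
# low-pass at the target Nyquist (windowed-sinc via fir1, DC gain
# normalized exactly), then take every q-th sample. Edges are handled by
# replication so constants are preserved exactly.
.resampleChannel <- function(x, p, q) {
  n <- length(x)
  taps <- 20L * q + 1L
  h <- signal::fir1(taps - 1L, 1 / q)
  h <- h * p / sum(h)
  padN <- ceiling(taps / p) + q
  xp <- c(rep(x[1L], padN), x, rep(x[n], padN))
  u <- numeric(length(xp) * p)
  u[seq(1L, by = p, length.out = length(xp))] <- xp
  y <- stats::convolve(u, rev(h), type = "open")
  delay <- (taps - 1L) / 2            # linear-phase group delay
  offset <- padN * p + delay
  nOut <- floor((n - 1L) * p / q) + 1L
  y[offset + 1L + (seq_len(nOut) - 1L) * q]
}

# Small rational approximation p/q of a ratio in (0, 1].
.ratApprox <- function(x, maxq = 10000L) {
  for (q in seq_len(maxq)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("resampling ratio has no small rational approximation")
}

#' Select trials by reaction time
#'
#' Keeps trials with `lo < reaction_time < hi` (strict inequalities),
#' preserving order.
#'
#' @param trials a [TrialTensor-class] with reaction times for every
#'   trial.
#' @param lo,hi bounds in seconds; defaults 0.6 and 2.8 (600-2800 ms).
#' @return the filtered [TrialTensor-class].
#' @export
filterTrialsByRT <- function(trials, lo = 0.6, hi = 2.8) {
  stopifnot(is(trials, "TrialTensor"))
  rt <- trials@events$reaction_time
  if (any(is.na(rt))) stop("reaction_time required for every trial")
  keep <- rt > lo & rt < hi
  if (!any(keep)) stop("no trials survive the reaction-time filter")
  trials[keep]
}

#' Region meta-electrodes via the leading principal component
#'
#' For each region (a named set of channels), computes the principal
#' components of the region's channels over all trials and samples pooled
#' (each channel mean-centered and scaled to unit variance), and projects
#' onto the leading component to form one meta-electrode channel. The
#' component sign is fixed so the mean loading is positive. Singleton
#' regions pass through unchanged.
#'
#' @param power a [TrialTensor-class].
#' @param groups named list mapping region name to channel indices or
#'   labels; groups must be disjoint and nonempty.
#' @return a [TrialTensor-class] with one channel per region.
#' @export
regionPrincipalComponent <- function(power, groups) {
  stopifnot(is(power, "TrialTensor"), length(groups) >= 1L)
  D <- nChannels(power)
  asIdx <- lapply(groups, function(g) {
    if (is.character(g)) match(g, channelLabels(power)) else as.integer(g)
  })
  if (any(vapply(asIdx, function(i) any(is.na(i)) || length(i) == 0L, TRUE)))
    stop("every group must name existing channels")
  if (anyDuplicated(unlist(asIdx))) stop("groups must be disjoint")
  pooled <- do.call(cbind, power@data)          # D x (sum T)
  Ts <- nSamples(power)
  outData <- lapply(Ts, function(T) matrix(0, length(groups), T))
  for (g in seq_along(asIdx)) {
    idx <- asIdx[[g]]
    if (length(idx) == 1L) {
      series <- pooled[idx, ]
    } else {
      M <- t(pooled[idx, , drop = FALSE])       # samples x channels
      pc <- stats::prcomp(M, center = TRUE, scale. = TRUE)
      flip <- if (mean(pc$rotation[, 1L]) < 0) -1 else 1
      series <- flip * as.numeric(pc$x[, 1L])
    }
    off <- 0L
    for (i in seq_along(Ts)) {
      outData[[i]][g, ] <- series[off + seq_len(Ts[i])]
      off <- off + Ts[i]
    }
  }
  TrialTensor(outData, rate = power@rate,
              channelLabels = names(groups), events = power@events)
}

#' Standard preprocessing pipeline
#'
#' Applies the canonical stage order: common-average reference, band-pass
#' Hilbert band power, prestimulus baseline normalization, resampling,
#' then reaction-time trial selection (and optionally region
#' meta-electrodes).
#'
#' @param raw a [TrialTensor-class] of raw recordings.
#' @param band a [BandSpec-class] (default broadband gamma 60-120 Hz with
#'   1-Hz flanks).
#' @param baselineWindow baseline window relative to stimulus (default
#'   `c(-0.7, -0.2)` s).
#' @param targetRate output rate in Hz (default 200).
#' @param rtRange keep trials with reaction times strictly inside this
#'   range (default `c(0.6, 2.8)` s); `NULL` skips the filter.
#' @param includeMask channels included in the common average.
#' @param groups optional region definition for
#'   [regionPrincipalComponent()].
#' @return the preprocessed [TrialTensor-class].
#' @export
preprocessTrials <- function(raw, band = bandSpec(),
                             baselineWindow = c(-0.7, -0.2),
                             targetRate = 200, rtRange = c(0.6, 2.8),
                             includeMask = NULL, groups = NULL) {
  x <- commonAverage(raw, includeMask)
  x <- bandpowerHilbert(x, band)
  x <- baselineNormalize(x, baselineWindow)
  x <- resampleTrials(x, targetRate)
  if (!is.null(rtRange)) x <- filterTrialsByRT(x, rtRange[1L], rtRange[2L])
  if (!is.null(groups)) x <- regionPrincipalComponent(x, groups)
  x
}
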