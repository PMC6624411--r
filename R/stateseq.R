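# Post-hoc analysis of decoded state sequences: raster construction,
# sliding-window majority filtering, cumulative state durations,
# language-state termination, and Fisher-transform correlation tests
# against behavior.

#' Decoded state raster from a fitted model
#'
#' Builds the per-trial most-probable-state raster: per-sample argmax of
#' the responsibilities (default, matching trial-raster displays), or the
#' Viterbi path with the corresponding responsibilities attached.
#'
#' @param fit an [ARHMMFit-class].
#' @param trials the [TrialTensor-class] the model was fit on (supplies
#'   rate and events; required for `method = "viterbi"`).
#' @param method `"gamma"` (per-sample argmax of responsibilities,
#'   default) or `"viterbi"`.
#' @return a [StateRaster-class].
#' @export
stateRaster <- function(fit, trials, method = c("gamma", "viterbi")) {
  method <- match.arg(method)
  stopifnot(is(fit, "ARHMMFit"), is(trials, "TrialTensor"))
  K <- nStates(fit@params)
  n <- length(fit@posterior@gamma)
  states <- vector("list", n)
  probs <- vector("list", n)
  for (i in seq_len(n)) {
    g <- fit@posterior@gamma[[i]]
    if (method == "gamma") {
      states[[i]] <- as.integer(max.col(g, ties.method = "first"))
    } else {
      states[[i]] <- viterbiPath(fit@params, trials, trial = i)
    }
    probs[[i]] <- g[cbind(seq_len(nrow(g)), states[[i]])]
  }
  new("StateRaster", states = states, probs = probs,
      rate = samplingRate(trials), events = trialEvents(trials),
      nStates = as.integer(K))
}

#' Raster of true simulated states
#'
#' Wraps a simulator ground truth as a [StateRaster-class] (probability 1
#' everywhere), so the same sequence analyses apply to truth and
#' estimate.
#'
#' @param truth a [GroundTruth-class].
#' @return a [StateRaster-class].
#' @export
truthStateRaster <- function(truth) {
  new("StateRaster", states = lapply(truth@stateRaster, as.integer),
      probs = lapply(truth@stateRaster, function(z) rep(1, length(z))),
      rate = samplingRate(truth@noiselessSignal),
      events = trialEvents(truth@noiselessSignal),
      nStates = as.integer(nStates(truth@params)))
}

# Modal state in a window of labels; ties resolved by larger summed
# responsibility, then by lower state index.
.windowMode <- function(z, p, K) {
  cnt <- tabulate(z, K)
  best <- which(cnt == max(cnt))
  if (length(best) > 1L) {
    ps <- vapply(best, function(s) sum(p[z == s]), 1)
    best <- best[ps == max(ps)]
  }
  best[1L]
}

#' Sliding-window majority filtering of a state raster
#'
#' Replaces each sample by the modal state within a centered window
#' (default 200 ms); windows are truncated at trial edges. Ties break
#' toward the state with the larger summed responsibility in the window,
#' then toward the lower state index.
#'
#' @param raster a [StateRaster-class].
#' @param window window length in seconds (default 0.2).
#' @return the filtered [StateRaster-class].
#' @export
majorityFilter <- function(raster, window = 0.2) {
  stopifnot(is(raster, "StateRaster"))
  w <- round(window * raster@rate)
  if (w < 2L) stop("window must span at least 2 samples")
  h <- floor(w / 2)
  states <- vector("list", length(raster@states))
  for (i in seq_along(raster@states)) {
    z <- raster@states[[i]]; p <- raster@probs[[i]]
    T <- length(z)
    out <- integer(T)
    for (t in seq_len(T)) {
      lo <- max(1L, t - h); hi <- min(T, t + h)
      out[t] <- .windowMode(z[lo:hi], p[lo:hi], raster@nStates)
    }
    states[[i]] <- out
  }
  new("StateRaster", states = states, probs = raster@probs,
      rate = raster@rate, events = raster@events,
      nStates = raster@nStates)
}

#' Cumulative per-state durations within a post-stimulus interval
#'
#' Sums the time assigned to each state within `[t0, t1)` relative to each
#' trial's stimulus onset; per trial the durations sum exactly to
#' `t1 - t0` (the interval must lie inside the trial).
#'
#' @param raster a [StateRaster-class] with stimulus onsets.
#' @param interval length-2 interval in seconds relative to stimulus
#'   onset; default `c(0, 3.2)`.
#' @return matrix `trials x states` of seconds.
#' @export
stateDurations <- function(raster, interval = c(0, 3.2)) {
  stopifnot(is(raster, "StateRaster"))
  stim <- raster@events$stimulus_onset
  if (any(is.na(stim))) stop("stimulus_onset required for every trial")
  n <- length(raster@states)
  out <- matrix(0, n, raster@nStates,
                dimnames = list(NULL, paste0("state", seq_len(raster@nStates))))
  for (i in seq_len(n)) {
    z <- raster@states[[i]]
    # half-open window [t0, t1) resolved to exact sample indices
    first <- round((stim[i] + interval[1L]) * raster@rate)
    count <- round((interval[2L] - interval[1L]) * raster@rate)
    if (first < 0L || first + count > length(z))
      stop("interval extends beyond trial ", i)
    sel <- first + seq_len(count)
    out[i, ] <- tabulate(z[sel], raster@nStates) / raster@rate
  }
  out
}

#' Termination time of a designated state
#'
#' For each trial, the latest center of a sliding window (default 100 ms)
#' between stimulus onset and articulation offset whose modal state
#' equals `targetState`; `NA` when no window qualifies.
#'
#' @param raster a [StateRaster-class] with stimulus and articulation
#'   markers.
#' @param targetState the state of interest (e.g., the language state).
#' @param window window length in seconds (default 0.1).
#' @return numeric vector of per-trial offset times in seconds (relative
#'   to trial start).
#' @export
languageOffset <- function(raster, targetState, window = 0.1) {
  stopifnot(is(raster, "StateRaster"))
  ev <- raster@events
  if (any(is.na(ev$articulation_offset)))
    stop("articulation_offset required for every trial")
  w <- max(2L, round(window * raster@rate))
  h <- floor(w / 2)
  out <- rep(NA_real_, length(raster@states))
  for (i in seq_along(raster@states)) {
    z <- raster@states[[i]]; p <- raster@probs[[i]]
    T <- length(z)
    tt <- (seq_len(T) - 1L) / raster@rate
    centers <- which(tt >= ev$stimulus_onset[i] &
                       tt <= ev$articulation_offset[i])
    for (t in rev(centers)) {
      lo <- max(1L, t - h); hi <- min(T, t + h)
      if (.windowMode(z[lo:hi], p[lo:hi], raster@nStates) == targetState) {
        out[i] <- tt[t]
        break
      }
    }
  }
  out
}

#' Pearson correlation with the Fisher-transform p value
#'
#' Two-sided test of zero correlation via the Fisher transform:
#' `p = 1 + erf(-(1/sqrt(2)) * arctanh(|r|) * sqrt(n - 3))`, which equals
#' `erfc(arctanh(|r|) * sqrt(n - 3) / sqrt(2))`.
#'
#' @param x,y numeric vectors of equal length `n >= 4` with nonzero
#'   variance.
#' @return list with `r`, `p`, `n`, and `degenerate` (TRUE when
#'   `|r| = 1`, where the transform diverges and the p value is clipped
#'   to 0).
#' @export
corrFisherP <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15)
    return(list(r = r, p = 0, n = n, degenerate = TRUE))
  # 1 + erf(-x) written as erfc(x), which keeps precision for small p
  p <- pracma::erfc(atanh(abs(r)) * sqrt(n - 3) / sqrt(2))
  list(r = r, p = p, n = n, degenerate = FALSE)
}

#' Correlations of state durations and language-state termination with
#' reaction time
#'
#' Majority-filters the raster, integrates per-state durations over the
#' post-stimulus interval, and correlates each state's duration -- plus
#' the termination time of the designated language state -- with the
#' per-trial reaction times.
#'
#' @param raster a [StateRaster-class] with events.
#' @param languageState state index treated as language processing
#'   (default 2).
#' @param interval duration-integration interval (default `c(0, 3.2)` s).
#' @param filterWindow majority-filter window (default 0.2 s); `NULL`
#'   skips filtering.
#' @param offsetWindow language-offset window (default 0.1 s).
#' @return data.frame with columns `state`, `statistic`, `r`, `p`, `n`;
#'   one row per state (duration vs RT) plus one `offset` row.
#' @export
durationBehaviorReport <- function(raster, languageState = 2L,
                                   interval = c(0, 3.2),
                                   filterWindow = 0.2,
                                   offsetWindow = 0.1) {
  stopifnot(is(raster, "StateRaster"))
  rt <- raster@events$reaction_time
  if (sum(is.finite(rt)) < 4L)
    stop("need at least 4 trials with reaction times")
  filt <- if (is.null(filterWindow)) raster else
    majorityFilter(raster, filterWindow)
  dur <- stateDurations(filt, interval)
  off <- languageOffset(filt, languageState, offsetWindow)
  rows <- list()
  for (z in seq_len(raster@nStates)) {
    cf <- tryCatch(corrFisherP(dur[, z], rt), error = function(e) NULL)
    if (!is.null(cf))
      rows[[length(rows) + 1L]] <- data.frame(
        state = z, statistic = "duration_vs_rt", r = cf$r, p = cf$p,
        n = cf$n)
  }
  # termination is referenced to stimulus onset, like the reaction time
  off <- off - raster@events$stimulus_onset
  cf <- tryCatch(corrFisherP(off, rt), error = function(e) NULL)
  if (!is.null(cf))
    rows[[length(rows) + 1L]] <- data.frame(
      state = languageState, statistic = "offset_vs_rt", r = cf$r,
      p = cf$p, n = cf$n)
  do.call(rbind, rows)
}
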