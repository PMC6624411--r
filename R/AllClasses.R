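#' @import methods
#' @importFrom stats var cor sd prcomp kmeans rnorm runif rgamma
#'   fft mvfft
#' @importFrom utils read.csv write.csv head
#' @useDynLib netstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.EVENT_COLS <- c("stimulus_onset", "articulation_onset",
                 "articulation_offset", "reaction_time")

#' TrialTensor: trial-structured multichannel time series
#'
#' The universal data carrier of the package: a list of channels-by-samples
#' matrices (one per trial) with a sampling rate, channel labels and
#' per-trial behavioral event markers. Times are in seconds from the start
#' of the trial; events may be `NA` where a marker is absent.
#'
#' @slot data list of numeric matrices, each `channels x samples`; the
#'   channel count is common to all trials, sample counts may differ.
#' @slot rate sampling rate in Hz.
#' @slot channelLabels character vector of channel names.
#' @slot events data.frame with one row per trial and columns
#'   `stimulus_onset`, `articulation_onset`, `articulation_offset`,
#'   `reaction_time` (seconds; `NA` allowed).
#'
#' @seealso [TrialTensor()] for the user constructor.
#' @exportClass TrialTensor
setClass("TrialTensor",
  representation(data = "list", rate = "numeric",
                 channelLabels = "character", events = "data.frame"))

setValidity("TrialTensor", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1L || !is.finite(object@rate) ||
      object@rate <= 0)
    msg <- c(msg, "rate must be a single positive finite number")
  if (length(object@data) == 0L)
    msg <- c(msg, "at least one trial is required")
  D <- vapply(object@data, nrow, 1L)
  if (length(unique(D)) > 1L)
    msg <- c(msg, "all trials must have the same number of channels")
  if (!all(vapply(object@data, function(m) all(is.finite(m)), TRUE)))
    msg <- c(msg, "trial data must be finite")
  if (length(object@channelLabels) != D[1L])
    msg <- c(msg, "channelLabels length must equal the channel count")
  ev <- object@events
  if (nrow(ev) != length(object@data))
    msg <- c(msg, "events must have one row per trial")
  if (!all(.EVENT_COLS %in% names(ev)))
    msg <- c(msg, paste("events must contain columns:",
                        paste(.EVENT_COLS, collapse = ", ")))
  if (length(msg) == 0L) {
    Tlen <- vapply(object@data, ncol, 1L) / object@rate
    for (col in setdiff(.EVENT_COLS, "reaction_time")) {
      v <- ev[[col]]
      bad <- !is.na(v) & (v < 0 | v > Tlen)
      if (any(bad))
        msg <- c(msg, sprintf("event '%s' outside trial bounds for trial(s) %s",
                              col, paste(which(bad), collapse = ",")))
    }
    both <- !is.na(ev$reaction_time) & !is.na(ev$stimulus_onset) &
      !is.na(ev$articulation_onset)
    if (any(both)) {
      dd <- abs(ev$reaction_time[both] -
                (ev$articulation_onset[both] - ev$stimulus_onset[both]))
      if (any(dd > 1e-9))
        msg <- c(msg, "reaction_time must equal articulation_onset - stimulus_onset")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ARHMMParams: the full switching-AR generative model
#'
#' Per-state autoregressive coefficient tensors, innovation covariances and
#' biases, plus the hidden-chain transition matrix and initial distribution.
#' State `z` emits `x_t = sum_tau A[z,tau,,] %*% x_{t-tau} + mu[z,] + e_t`
#' with `e_t ~ N(0, Q[z,,])`.
#'
#' @slot A numeric array `K x order x D x D`; `A[z,tau,j,k]` is the influence
#'   of channel `k` at lag `tau` on channel `j` in state `z`.
#' @slot Q numeric array `K x D x D` of symmetric positive-definite
#'   innovation covariances.
#' @slot mu numeric matrix `K x D` of state-dependent biases.
#' @slot trans `K x K` row-stochastic transition matrix.
#' @slot initDist length-`K` initial state distribution.
#'
#' @exportClass ARHMMParams
setClass("ARHMMParams",
  representation(A = "array", Q = "array", mu = "matrix",
                 trans = "matrix", initDist = "numeric"))

setValidity("ARHMMParams", function(object) {
  msg <- character(0)
  dA <- dim(object@A)
  if (length(dA) != 4L) return("A must be a K x order x D x D array")
  K <- dA[1L]; D <- dA[3L]
  if (dA[4L] != D) msg <- c(msg, "A must be square in its channel axes")
  if (!identical(dim(object@Q), c(K, D, D)))
    msg <- c(msg, "Q must be K x D x D")
  if (!identical(dim(object@mu), c(K, D)))
    msg <- c(msg, "mu must be K x D")
  if (!identical(dim(object@trans), c(K, K)))
    msg <- c(msg, "trans must be K x K")
  if (length(object@initDist) != K)
    msg <- c(msg, "initDist must have length K")
  if (length(msg) == 0L) {
    if (any(abs(rowSums(object@trans) - 1) > 1e-12) || any(object@trans < 0))
      msg <- c(msg, "trans rows must be nonnegative and sum to 1")
    if (abs(sum(object@initDist) - 1) > 1e-12 || any(object@initDist < 0))
      msg <- c(msg, "initDist must be a probability vector")
    for (z in seq_len(K)) {
      Qz <- object@Q[z, , , drop = TRUE]
      Qz <- matrix(Qz, D, D)
      if (max(abs(Qz - t(Qz))) > 1e-8 ||
          inherits(try(chol(Qz), silent = TRUE), "try-error"))
        msg <- c(msg, sprintf("Q for state %d is not symmetric positive-definite", z))
    }
  }
  if (length(msg)) msg else TRUE
})

#' StatePosterior: smoothed state marginals from the E-step
#'
#' @slot gamma list (one per trial) of `T x K` matrices of responsibilities
#'   `P(z_t | x_{1:T})`; each row sums to 1.
#' @slot xi list (one per trial) of `(T-1) x K x K` arrays of pairwise
#'   marginals `P(z_t, z_{t+1} | x_{1:T})`; each time slice sums to 1.
#' @slot loglik total log-likelihood of all trials.
#'
#' @exportClass StatePosterior
setClass("StatePosterior",
  representation(gamma = "list", xi = "list", loglik = "numeric"))

setValidity("StatePosterior", function(object) {
  msg <- character(0)
  if (length(object@gamma) != length(object@xi))
    msg <- c(msg, "gamma and xi must have one entry per trial")
  for (i in seq_along(object@gamma)) {
    g <- object@gamma[[i]]
    if (any(abs(rowSums(g) - 1) > 1e-9))
      msg <- c(msg, sprintf("gamma rows of trial %d do not sum to 1", i))
    x <- object@xi[[i]]
    if (length(x) && any(abs(apply(x, 1L, sum) - 1) > 1e-9))
      msg <- c(msg, sprintf("xi slices of trial %d do not sum to 1", i))
  }
  if (length(msg)) msg else TRUE
})

#' ARHMMFit: result of Baum-Welch expectation-maximization
#'
#' @slot params fitted [ARHMMParams-class].
#' @slot posterior [StatePosterior-class] under the fitted parameters.
#' @slot loglikTrace per-iteration log-likelihood (non-decreasing up to
#'   numerical tolerance).
#' @slot converged logical flag.
#' @slot niter number of EM iterations run.
#'
#' @exportClass ARHMMFit
setClass("ARHMMFit",
  representation(params = "ARHMMParams", posterior = "StatePosterior",
                 loglikTrace = "numeric", converged = "logical",
                 niter = "integer"))

#' SimConfig: study design of the switching-AR simulator
#'
#' @slot nStates number of latent states.
#' @slot nChannels number of channels.
#' @slot arOrder autoregressive order (lags).
#' @slot nTrials number of trials.
#' @slot trialLength samples per trial.
#' @slot rate sampling rate in Hz (for event bookkeeping).
#' @slot scheduleMode one of `"markov"`, `"fixed_blocks"`,
#'   `"variable_blocks"`.
#' @slot snr observation signal-to-noise ratio (variance ratio); `Inf`
#'   means no observation noise.
#' @slot meanNoiseGain gain of the mean-dependent process-noise
#'   modulation (alpha).
#' @slot selfTransition diagonal mass of the generating transition matrix
#'   (markov schedule).
#' @slot seed integer RNG seed.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nStates = "integer", nChannels = "integer",
                 arOrder = "integer", nTrials = "integer",
                 trialLength = "integer", rate = "numeric",
                 scheduleMode = "character", snr = "numeric",
                 meanNoiseGain = "numeric", selfTransition = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nStates < 1L) msg <- c(msg, "nStates must be >= 1")
  if (object@arOrder < 1L) msg <- c(msg, "arOrder must be >= 1")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@trialLength <= object@arOrder)
    msg <- c(msg, "trialLength must exceed arOrder")
  if (!(object@scheduleMode %in% c("markov", "fixed_blocks", "variable_blocks")))
    msg <- c(msg, "unknown scheduleMode")
  if (!(object@snr > 0)) msg <- c(msg, "snr must be > 0 (possibly Inf)")
  if (object@meanNoiseGain < 0) msg <- c(msg, "meanNoiseGain must be >= 0")
  if (object@selfTransition <= 0 || object@selfTransition >= 1)
    msg <- c(msg, "selfTransition must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: the simulator's reference for parameter recovery
#'
#' @slot params generating [ARHMMParams-class].
#' @slot stateRaster list (one per trial) of integer state sequences, one
#'   entry per sample.
#' @slot noiselessSignal the simulated [TrialTensor-class] before
#'   observation noise.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(params = "ARHMMParams", stateRaster = "list",
                 noiselessSignal = "TrialTensor"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  K <- dim(object@params@A)[1L]
  n <- length(object@noiselessSignal@data)
  if (length(object@stateRaster) != n)
    msg <- c(msg, "stateRaster must have one sequence per trial")
  for (i in seq_along(object@stateRaster)) {
    r <- object@stateRaster[[i]]
    if (length(r) != ncol(object@noiselessSignal@data[[i]]))
      msg <- c(msg, sprintf("raster length mismatch in trial %d", i))
    if (any(r < 1L | r > K))
      msg <- c(msg, sprintf("raster states outside 1..K in trial %d", i))
  }
  if (length(msg)) msg else TRUE
})

#' BandSpec: a band-pass specification with sigmoid flanks
#'
#' @slot fLo lower band edge (Hz).
#' @slot fHi upper band edge (Hz).
#' @slot flankHalfwidth logistic flank half-width (Hz).
#'
#' @exportClass BandSpec
setClass("BandSpec",
  representation(fLo = "numeric", fHi = "numeric",
                 flankHalfwidth = "numeric"))

setValidity("BandSpec", function(object) {
  if (object@fLo <= 0 || object@fHi <= object@fLo)
    return("need 0 < fLo < fHi")
  if (object@flankHalfwidth <= 0)
    return("flankHalfwidth must be positive")
  TRUE
})

#' WindowedMVAR: sliding-window adaptive MVAR estimates
#'
#' @slot windows `W x 2` matrix of window start/end times (seconds from
#'   trial start).
#' @slot coeffs numeric array `W x order x D x D`.
#' @slot noiseCov numeric array `W x D x D` of residual covariances.
#' @slot bias numeric matrix `W x D` of intercepts.
#' @slot order autoregressive order.
#'
#' @exportClass WindowedMVAR
setClass("WindowedMVAR",
  representation(windows = "matrix", coeffs = "array",
                 noiseCov = "array", bias = "matrix", order = "integer"))

#' PDCSpectrum: frequency-resolved partial directed coherence
#'
#' Entry `(f, j, k)` is the complex PDC from source channel `k` to target
#' channel `j` at frequency `freqs[f]`; every column satisfies
#' `sum_j |pi_jk(f)|^2 = 1`.
#'
#' @slot freqs frequency grid (Hz).
#' @slot values complex array `F x D x D`.
#' @slot rate sampling rate (Hz) that normalizes the frequency axis.
#'
#' @exportClass PDCSpectrum
setClass("PDCSpectrum",
  representation(freqs = "numeric", values = "array", rate = "numeric"))

#' IntegratedPDC: PDC magnitude integrated over a frequency band
#'
#' @slot matrix `D x D` nonnegative matrix; entry `(j,k)` integrates
#'   `|pi_jk(f)|` over the band.
#' @slot band length-2 numeric band (Hz).
#'
#' @exportClass IntegratedPDC
setClass("IntegratedPDC",
  representation(matrix = "matrix", band = "numeric"))

#' StateRaster: decoded state sequences with behavioral markers
#'
#' @slot states list (one per trial) of integer most-probable-state
#'   sequences.
#' @slot probs list (one per trial) of the corresponding maximum
#'   responsibilities in `[0, 1]`.
#' @slot rate sampling rate (Hz).
#' @slot events per-trial behavioral markers (same schema as
#'   [TrialTensor-class]).
#' @slot nStates number of model states.
#'
#' @exportClass StateRaster
setClass("StateRaster",
  representation(states = "list", probs = "list", rate = "numeric",
                 events = "data.frame", nStates = "integer"))

setValidity("StateRaster", function(object) {
  msg <- character(0)
  for (i in seq_along(object@states)) {
    if (any(object@states[[i]] < 1L | object@states[[i]] > object@nStates))
      msg <- c(msg, sprintf("states outside 1..K in trial %d", i))
    p <- object@probs[[i]]
    if (any(p < -1e-12 | p > 1 + 1e-12))
      msg <- c(msg, sprintf("probs outside [0,1] in trial %d", i))
  }
  if (length(msg)) msg else TRUE
})

#' WhitenessReport: residual autocorrelation diagnostics
#'
#' @slot lags integer lags examined (1..order; lag zero is excluded).
#' @slot corr numeric array `L x D x D` of pooled lagged residual
#'   correlations.
#' @slot maxAbs maximum absolute correlation across lags and channel pairs.
#' @slot threshold pass threshold on `|corr|` (default `3/sqrt(N)`).
#' @slot passFrac fraction of entries with `|corr|` below threshold.
#' @slot pass TRUE when `passFrac >= 0.95`.
#' @slot n pooled sample count behind each correlation.
#'
#' @exportClass WhitenessReport
setClass("WhitenessReport",
  representation(lags = "integer", corr = "array", maxAbs = "numeric",
                 threshold = "numeric", passFrac = "numeric",
                 pass = "logical", n = "integer"))
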