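# Switching-AR simulator with known ground truth. Emulates the
# robustness-study design: state-specific stable AR dynamics with distinct
# directed networks, variable state durations across trials,
# mean-dependent process noise, and additive observation noise at a
# controlled SNR.

#' Build a simulation configuration
#'
#' @param nStates number of latent states (default 3).
#' @param nChannels number of channels (default 6).
#' @param arOrder AR order (default 2).
#' @param nTrials number of trials (default 100).
#' @param trialLength samples per trial (default 400).
#' @param rate sampling rate in Hz (default 200).
#' @param scheduleMode `"variable_blocks"` (default; an ordered pass
#'   through the states with trial-varying durations), `"markov"`, or
#'   `"fixed_blocks"`.
#' @param snr observation signal-to-noise variance ratio; `Inf` (default)
#'   adds no observation noise.
#' @param meanNoiseGain gain `alpha` of the mean-dependent process-noise
#'   modulation `sigma_t = sigma_0 (1 + alpha |mean_c x_{c,t-1}|)`
#'   (default 0.5).
#' @param selfTransition diagonal mass of the generating transition
#'   matrix (default 0.98).
#' @param seed integer seed (default 1).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nStates = 3L, nChannels = 6L, arOrder = 2L,
                      nTrials = 100L, trialLength = 400L, rate = 200,
                      scheduleMode = c("variable_blocks", "markov",
                                       "fixed_blocks"),
                      snr = Inf, meanNoiseGain = 0.5,
                      selfTransition = 0.98, seed = 1L) {
  new("SimConfig", nStates = as.integer(nStates),
      nChannels = as.integer(nChannels), arOrder = as.integer(arOrder),
      nTrials = as.integer(nTrials), trialLength = as.integer(trialLength),
      rate = as.numeric(rate), scheduleMode = match.arg(scheduleMode),
      snr = as.numeric(snr), meanNoiseGain = as.numeric(meanNoiseGain),
      selfTransition = as.numeric(selfTransition), seed = as.integer(seed))
}

# One random stable sparse coefficient tensor with target companion
# spectral radius rho: Gaussian entries, off-diagonal sparsity mask, then
# the lag-tau block is scaled by c^tau so eigenvalues scale by c.
.randomStableA <- function(D, P, rho, sparsity = 0.4) {
  A <- array(stats::rnorm(P * D * D, 0, 1 / sqrt(D)), c(P, D, D))
  if (D > 1L) {
    mask <- matrix(stats::runif(D * D) < sparsity, D, D)
    diag(mask) <- TRUE
    for (tau in seq_len(P)) A[tau, , ] <- A[tau, , ] * mask
  }
  sr <- spectralRadius(A)
  if (sr < 1e-12) return(NULL)
  cc <- rho / sr
  for (tau in seq_len(P)) A[tau, , ] <- A[tau, , ] * cc^tau
  A
}

#' Draw ground-truth ARHMM parameters for a simulation design
#'
#' Rejection-samples per-state AR tensors until every state is stable
#' (companion spectral radius below `1 - margin`) and all state pairs are
#' distinct in their directed-network fingerprints (frequency-integrated
#' PDC dissimilarity above `minDissim`). The transition matrix is
#' row-stochastic with dominant diagonal.
#'
#' @param config a [SimConfig-class].
#' @param margin stability margin (default 0.01: radii are drawn in
#'   0.7-0.95, checked below 0.99).
#' @param minDissim minimum pairwise integrated-PDC dissimilarity between
#'   states (default 0.1).
#' @param maxAttempts rejection-sampling budget per state (default 200).
#' @return an [ARHMMParams-class].
#' @export
makeGroundTruthParams <- function(config, margin = 0.01, minDissim = 0.1,
                                  maxAttempts = 200L) {
  stopifnot(is(config, "SimConfig"))
  K <- config@nStates; D <- config@nChannels; P <- config@arOrder
  .withSeed(deriveSeed(config@seed, "params"), {
    A <- array(0, c(K, P, D, D))
    ipdc <- vector("list", K)
    grid <- seq(0, config@rate / 2, length.out = 64L)
    for (z in seq_len(K)) {
      ok <- FALSE
      for (attempt in seq_len(maxAttempts)) {
        rho <- stats::runif(1, 0.7, 0.95)
        Az <- .randomStableA(D, P, rho)
        if (is.null(Az) || spectralRadius(Az) >= 1 - margin) next
        cand <- integratePDC(pdc(Az, grid, config@rate))
        distinct <- TRUE
        for (zz in seq_len(z - 1L))
          if (pdcDissimilarity(cand, ipdc[[zz]]) <= minDissim)
            distinct <- FALSE
        if (distinct) {
          A[z, , , ] <- Az
          ipdc[[z]] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not draw ", K, " stable, pairwise-distinct states ",
             "within ", maxAttempts, " attempts; relax the configuration")
    }
    Q <- array(0, c(K, D, D))
    for (z in seq_len(K)) {
      R <- matrix(stats::rnorm(D * D, 0, 0.1), D, D)
      Q[z, , ] <- diag(0.05, D) + crossprod(R) / D
    }
    mu <- matrix(stats::rnorm(K * D, 0, 0.3), K, D)
    p <- config@selfTransition
    trans <- if (K == 1L) matrix(1, 1, 1) else
      matrix((1 - p) / (K - 1), K, K) + diag(p - (1 - p) / (K - 1), K)
    initDist <- c(1, rep(0, K - 1L))
    if (config@scheduleMode == "markov" && K > 1L)
      initDist <- rep(1 / K, K)
    new("ARHMMParams", A = A, Q = Q, mu = mu, trans = trans,
        initDist = initDist)
  })
}

# Per-trial latent schedule of length T.
.makeSchedule <- function(config, params) {
  K <- config@nStates; T <- config@trialLength
  switch(config@scheduleMode,
    markov = {
      z <- integer(T)
      z[1L] <- sample.int(K, 1L, prob = params@initDist)
      for (t in 2L:T)
        z[t] <- sample.int(K, 1L, prob = params@trans[z[t - 1L], ])
      z
    },
    fixed_blocks = {
      rep(seq_len(K), times = diff(round(seq(0, T, length.out = K + 1L))))
    },
    variable_blocks = {
      # ordered pass through the states with trial-varying durations
      minLen <- max(2L * config@arOrder + 5L, floor(T / (4L * K)))
      repeat {
        w <- stats::rgamma(K, shape = 4)
        len <- floor(w / sum(w) * T)
        len[K] <- T - sum(len[-K])
        if (all(len >= minLen)) break
      }
      rep(seq_len(K), times = len)
    })
}

# Draw the initial `order` samples from the stationary law of the first
# scheduled state; falls back to zeros plus a discarded burn-in when the
# Lyapunov solve fails.
.initialSamples <- function(params, z0, P, D) {
  A <- arCoefficients(params, z0)
  Q <- noiseCovariance(params, z0)
  mu <- stateBias(params, z0)
  X0 <- tryCatch({
    Sig <- .stationaryCompanionCov(A, Q)
    m <- .stationaryMean(A, mu)
    L <- chol(Sig + diag(1e-10, nrow(Sig)))
    s <- as.numeric(crossprod(L, stats::rnorm(nrow(Sig)))) +
      rep(m, P)
    # companion state stacks (x_t, x_{t-1}, ...); unstack to columns
    matrix(s, D, P)[, P:1L, drop = FALSE]
  }, error = function(e) NULL)
  if (!is.null(X0)) return(list(X = X0, burn = 0L))
  list(X = matrix(0, D, P), burn = 50L)
}

#' Simulate a switching-AR dataset with ground truth
#'
#' Iterates the state-conditional AR recursion under a per-trial latent
#' schedule, applies the mean-dependent process-noise modulation, then
#' adds observation noise at the configured SNR. Behavioral events are
#' synthesized so that the designated "language" state (state 2 when
#' `K >= 3`, else the last state) determines the trial's reaction time:
#' stimulus onset is placed at the end of the first state block and
#' articulation onset at the end of that designated state's block.
#'
#' @param params generating [ARHMMParams-class] (e.g., from
#'   [makeGroundTruthParams()]).
#' @param config the [SimConfig-class].
#' @return list with `observed` (a [TrialTensor-class], observation noise
#'   included), and `truth` (a [GroundTruth-class] holding the generating
#'   parameters, the per-trial state raster and the noiseless signal).
#' @export
simulateDataset <- function(params, config) {
  stopifnot(is(params, "ARHMMParams"), is(config, "SimConfig"))
  K <- config@nStates; D <- config@nChannels; P <- config@arOrder
  T <- config@trialLength
  for (z in seq_len(K))
    if (spectralRadius(arCoefficients(params, z)) >= 1)
      stop("unstable generating parameters for state ", z)
  chQ <- lapply(seq_len(K), function(z)
    chol(noiseCovariance(params, z)))
  alpha <- config@meanNoiseGain
  data <- vector("list", config@nTrials)
  raster <- vector("list", config@nTrials)
  ev <- data.frame(stimulus_onset = rep(NA_real_, config@nTrials),
                   articulation_onset = NA_real_,
                   articulation_offset = NA_real_,
                   reaction_time = NA_real_)
  langState <- if (K >= 3L) 2L else K
  .withSeed(deriveSeed(config@seed, "simulate"), {
    for (i in seq_len(config@nTrials)) {
      z <- .makeSchedule(config, params)
      ini <- .initialSamples(params, z[1L], P, D)
      burn <- ini$burn
      Ttot <- T + burn
      X <- matrix(0, D, Ttot)
      X[, seq_len(P)] <- ini$X
      zfull <- c(rep(z[1L], burn), z)
      for (t in (P + 1L):Ttot) {
        zt <- zfull[t]
        m <- stateBias(params, zt)
        Az <- params@A
        for (tau in seq_len(P))
          m <- m + matrix(Az[zt, tau, , ], D, D) %*% X[, t - tau]
        s <- 1 + alpha * abs(mean(X[, t - 1L]))
        X[, t] <- m + s * as.numeric(crossprod(chQ[[zt]],
                                               stats::rnorm(D)))
        if (!all(is.finite(X[, t])))
          stop("numerical overflow while simulating trial ", i,
               "; parameters appear unstable")
      }
      X <- X[, burn + seq_len(T), drop = FALSE]
      data[[i]] <- X
      raster[[i]] <- z
      blocks <- rle(z)
      ends <- cumsum(blocks$lengths) / config@rate
      if (K >= 2L && blocks$values[1L] == 1L) {
        stim <- ends[1L]
        li <- which(blocks$values == langState)
        if (length(li)) {
          ev$stimulus_onset[i] <- stim
          ev$articulation_onset[i] <- ends[max(li)]
          ev$articulation_offset[i] <- min(T / config@rate,
                                           ends[max(li)] + 0.4)
          ev$reaction_time[i] <- ends[max(li)] - stim
        }
      }
    }
  })
  labels <- paste0("ch", seq_len(D))
  clean <- TrialTensor(data, rate = config@rate, channelLabels = labels,
                       events = ev)
  truth <- new("GroundTruth", params = params, stateRaster = raster,
               noiselessSignal = clean)
  observed <- if (is.finite(config@snr))
    corruptObservations(clean, snr = config@snr,
                        seed = deriveSeed(config@seed, "obsnoise"))
  else clean
  list(observed = observed, truth = truth)
}

#' Add white observation noise at a controlled SNR
#'
#' Adds i.i.d. Gaussian noise per channel, scaled so that each channel's
#' ratio `var(signal) / var(noise)` (signal variance pooled over trials)
#' equals `snr`; the channel-mean ratio therefore equals `snr` as well.
#' `snr = Inf` returns the input unchanged.
#'
#' @param clean a noiseless [TrialTensor-class].
#' @param snr positive variance ratio (may be `Inf`).
#' @param seed integer seed.
#' @return a [TrialTensor-class] with observation noise added.
#' @export
corruptObservations <- function(clean, snr, seed = 1L) {
  stopifnot(is(clean, "TrialTensor"))
  if (!(snr > 0)) stop("snr must be positive")
  if (!is.finite(snr)) return(clean)
  pooled <- do.call(cbind, clean@data)
  sdNoise <- sqrt(apply(pooled, 1L, var) / snr)
  .withSeed(seed, {
    noisy <- lapply(clean@data, function(X)
      X + sdNoise * matrix(stats::rnorm(length(X)), nrow(X)))
    new("TrialTensor", data = noisy, rate = clean@rate,
        channelLabels = clean@channelLabels, events = clean@events)
  })
}

#' @describeIn simulateDataset accessor: generating parameters of a
#'   ground-truth object
#' @param truth a [GroundTruth-class]
#' @export
truthParams <- function(truth) truth@params

#' @describeIn simulateDataset accessor: per-trial true state raster
#' @export
truthRaster <- function(truth) truth@stateRaster

#' @describeIn simulateDataset accessor: noiseless simulated signal
#' @export
truthSignal <- function(truth) truth@noiselessSignal
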