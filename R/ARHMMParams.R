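#' Construct ARHMMParams
#'
#' @param A coefficient array `K x order x D x D` (or `order x D x D` for a
#'   single state).
#' @param Q innovation covariances `K x D x D` (or a single `D x D` matrix
#'   recycled over states).
#' @param mu `K x D` matrix of state biases (default zero).
#' @param trans `K x K` row-stochastic transition matrix (default: sticky
#'   uniform with 0.9 self-transition mass, or `[1]` for `K = 1`).
#' @param initDist initial state distribution (default uniform).
#' @return an [ARHMMParams-class] object.
#' @examples
#' p <- ARHMMParams(array(0.5, c(1, 1, 1, 1)), array(1, c(1, 1, 1)))
#' nStates(p); arOrder(p)
#' @export
ARHMMParams <- function(A, Q, mu = NULL, trans = NULL, initDist = NULL) {
  if (length(dim(A)) == 3L) A <- array(A, c(1L, dim(A)))
  K <- dim(A)[1L]; D <- dim(A)[3L]
  if (is.matrix(Q)) Q <- aperm(array(Q, c(D, D, K)), c(3L, 1L, 2L))
  if (is.null(mu)) mu <- matrix(0, K, D)
  if (is.null(trans)) {
    trans <- if (K == 1L) matrix(1, 1, 1) else
      matrix(0.1 / (K - 1), K, K) + diag(0.9 - 0.1 / (K - 1), K)
  }
  if (is.null(initDist)) initDist <- rep(1 / K, K)
  new("ARHMMParams", A = A, Q = Q, mu = as.matrix(mu),
      trans = as.matrix(trans), initDist = as.numeric(initDist))
}

#' @describeIn ARHMMParams number of latent states
#' @param x an `ARHMMParams`
#' @export
setMethod("nStates", "ARHMMParams", function(x) dim(x@A)[1L])

#' @describeIn ARHMMParams number of channels
#' @export
setMethod("nChannels", "ARHMMParams", function(x) dim(x@A)[3L])

#' @describeIn ARHMMParams autoregressive order
#' @export
setMethod("arOrder", "ARHMMParams", function(x) dim(x@A)[2L])

#' @describeIn ARHMMParams lag-indexed coefficient array
#'   `order x D x D` of one state
#' @param state state index
#' @export
setMethod("arCoefficients", "ARHMMParams", function(x, state) {
  array(x@A[state, , , ], dim(x@A)[-1L])
})

#' @describeIn ARHMMParams innovation covariance of one state
#' @export
setMethod("noiseCovariance", "ARHMMParams", function(x, state) {
  D <- nChannels(x)
  matrix(x@Q[state, , ], D, D)
})

#' @describeIn ARHMMParams bias vector of one state
#' @export
setMethod("stateBias", "ARHMMParams", function(x, state) x@mu[state, ])

#' @describeIn ARHMMParams row-stochastic transition matrix
#' @export
setMethod("transitionMatrix", "ARHMMParams", function(x) x@trans)

#' @describeIn ARHMMParams initial state distribution
#' @export
setMethod("initialDistribution", "ARHMMParams", function(x) x@initDist)

setMethod("show", "ARHMMParams", function(object) {
  cat(sprintf("ARHMMParams: %d state(s), %d channel(s), AR order %d\n",
              nStates(object), nChannels(object), arOrder(object)))
  cat("  transition diagonal:",
      paste(sprintf("%.3f", diag(object@trans)), collapse = " "), "\n")
})

#' @describeIn StatePosterior responsibilities of trial `i` (`T x K`)
#' @param x a `StatePosterior`
#' @param i trial index
#' @export
setMethod("responsibilities", "StatePosterior", function(x, i) x@gamma[[i]])

#' @describeIn StatePosterior pairwise marginals of trial `i`
#'   (`(T-1) x K x K`)
#' @export
setMethod("pairwiseMarginals", "StatePosterior", function(x, i) x@xi[[i]])

#' @describeIn StatePosterior total log-likelihood
#' @export
setMethod("totalLogLik", "StatePosterior", function(x) x@loglik)

setMethod("show", "StatePosterior", function(object) {
  cat(sprintf("StatePosterior: %d trial(s), %d state(s), loglik %.4f\n",
              length(object@gamma), ncol(object@gamma[[1L]]),
              object@loglik))
})

#' @describeIn ARHMMFit fitted parameters
#' @param x an `ARHMMFit`
#' @export
setMethod("fittedParams", "ARHMMFit", function(x) x@params)

#' @describeIn ARHMMFit posterior under the fitted parameters
#' @export
setMethod("posterior", "ARHMMFit", function(x) x@posterior)

#' @describeIn ARHMMFit per-iteration log-likelihood trace
#' @export
setMethod("loglikTrace", "ARHMMFit", function(x) x@loglikTrace)

#' @describeIn ARHMMFit final log-likelihood
#' @export
setMethod("totalLogLik", "ARHMMFit", function(x) x@posterior@loglik)

setMethod("show", "ARHMMFit", function(object) {
  cat(sprintf(
    "ARHMMFit: %d state(s), order %d; loglik %.4f after %d iteration(s)%s\n",
    nStates(object@params), arOrder(object@params),
    object@posterior@loglik, object@niter,
    if (object@converged) " (converged)" else ""))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d state(s) x %d channel(s), order %d; %d trial(s) x %d samples @ %g Hz\n",
    object@nStates, object@nChannels, object@arOrder, object@nTrials,
    object@trialLength, object@rate))
  cat(sprintf("  schedule %s, SNR %g, mean-noise gain %g, seed %d\n",
              object@scheduleMode, object@snr, object@meanNoiseGain,
              object@seed))
})

setMethod("show", "PDCSpectrum", function(object) {
  cat(sprintf("PDCSpectrum: %d frequencies on [%g, %g] Hz, %d channels\n",
              length(object@freqs), min(object@freqs), max(object@freqs),
              dim(object@values)[2L]))
})

setMethod("show", "IntegratedPDC", function(object) {
  cat(sprintf("IntegratedPDC over [%g, %g] Hz:\n",
              object@band[1L], object@band[2L]))
  print(round(object@matrix, 4L))
})

setMethod("show", "WhitenessReport", function(object) {
  cat(sprintf(
    "WhitenessReport: lags %s; max |corr| %.4g, threshold %.4g; %.1f%% below -> %s\n",
    paste(range(object@lags), collapse = "-"), object@maxAbs,
    object@threshold, 100 * object@passFrac,
    if (object@pass) "PASS" else "FAIL"))
})
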