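# Switching-AR hidden Markov model: conditional emission likelihood,
# exact forward-backward smoothing, sticky M-step, EM driver, Viterbi
# decoding and BIC/held-out model selection.
#
# The emission model is conditional: within each trial the first `order`
# samples are conditioned on, not modeled, so their emission log-density
# is zero for every state and the latent chain still runs over the full
# trial.

#' Per-sample emission log-likelihood under every state
#'
#' Computes `log N(x_t; sum_tau A[z,tau,,] x_{t-tau} + mu_z, Q_z)` for
#' every sample `t` and state `z` of one trial. The first `order` samples
#' are conditioned on and contribute zero.
#'
#' @param params an [ARHMMParams-class].
#' @param x a `channels x samples` matrix (one trial), or a
#'   [TrialTensor-class] together with `trial`.
#' @param trial trial index when `x` is a `TrialTensor`.
#' @return a `T x K` matrix of log-densities.
#' @export
emissionLoglik <- function(params, x, trial = 1L) {
  if (is(x, "TrialTensor")) x <- trialData(x, trial)
  P <- arOrder(params)
  if (ncol(x) <= P) stop("trial must be longer than the AR order")
  des <- .lagDesign(x, P)
  logB <- matrix(0, ncol(x), nStates(params))
  logB[(P + 1L):ncol(x), ] <- .emissionCore(params, des)
  logB
}

# Emission log-density rows for the regressed samples of one design.
.emissionCore <- function(params, des) {
  K <- nStates(params); D <- nChannels(params); P <- arOrder(params)
  n <- nrow(des$Y)
  out <- matrix(0, n, K)
  for (z in seq_len(K)) {
    B <- .packB(arCoefficients(params, z), stateBias(params, z))
    Qz <- noiseCovariance(params, z)
    ch <- tryCatch(chol(Qz), error = function(e)
      stop("innovation covariance of state ", z,
           " is not positive-definite"))
    E <- des$Y - des$Z %*% B
    W <- backsolve(ch, t(E), transpose = TRUE)
    out[, z] <- -0.5 * (D * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          colSums(W^2))
  }
  out
}

#' Exact forward-backward smoothing for one sequence
#'
#' Scaled (underflow-free) forward-backward on precomputed emission
#' log-densities; returns smoothed marginals, pairwise marginals and the
#' sequence log-likelihood.
#'
#' @param logB `T x K` emission log-density matrix.
#' @param trans `K x K` row-stochastic transition matrix.
#' @param initDist length-`K` initial distribution.
#' @return a [StatePosterior-class] holding this one sequence.
#' @export
forwardBackward <- function(logB, trans, initDist) {
  logB <- as.matrix(logB)
  if (any(!is.finite(logB) & logB > -Inf))
    stop("logB must be finite or -Inf")
  res <- forward_backward_cpp(logB, as.matrix(trans),
                              as.numeric(initDist))
  xi <- res$xi
  xi <- if (length(xi)) aperm(xi, c(3L, 1L, 2L)) else
    array(0, c(0L, ncol(logB), ncol(logB)))
  new("StatePosterior", gamma = list(res$gamma), xi = list(xi),
      loglik = res$loglik)
}

# E-step over all trials from precomputed designs.
.eStep <- function(params, designs, Tlens) {
  P <- arOrder(params); K <- nStates(params)
  gam <- vector("list", length(designs))
  xis <- vector("list", length(designs))
  ll <- 0
  for (i in seq_along(designs)) {
    logB <- matrix(0, Tlens[i], K)
    logB[(P + 1L):Tlens[i], ] <- .emissionCore(params, designs[[i]])
    res <- forward_backward_cpp(logB, params@trans, params@initDist)
    gam[[i]] <- res$gamma
    xis[[i]] <- res$xi           # K x K x (T-1) cube; summed later
    ll <- ll + res$loglik
  }
  list(gamma = gam, xi = xis, loglik = ll)
}

#' Sticky smoothing of a transition matrix
#'
#' Applies the self-transition pseudocount prior
#' `(trans + u I) / (1 + u)`, which lower-bounds the diagonal at
#' `u / (1 + u)` and leaves the identity matrix fixed.
#'
#' @param trans row-stochastic matrix.
#' @param u nonnegative stickiness; `u = 0` is the identity map.
#' @return the smoothed row-stochastic matrix.
#' @export
smoothTransitions <- function(trans, u) {
  stopifnot(u >= 0)
  (trans + diag(u, nrow(trans))) / (1 + u)
}

#' Maximization step of the ARHMM EM
#'
#' Given responsibilities, solves the responsibility-weighted least-squares
#' regression pooled over all trials for each state's coefficients and
#' bias, the weighted residual covariance, the smoothed transition matrix
#' and the initial distribution.
#'
#' @param trials a [TrialTensor-class].
#' @param posterior a [StatePosterior-class] aligned with `trials`.
#' @param order AR order.
#' @param u stickiness (self-transition pseudocount weight); default 0.5.
#' @param prev optional previous [ARHMMParams-class] used to rescue
#'   collapsed states.
#' @param diagQ logical; constrain innovation covariances to be diagonal.
#' @return an [ARHMMParams-class].
#' @export
mStep <- function(trials, posterior, order, u = 0.5, prev = NULL,
                  diagQ = FALSE) {
  designs <- lapply(trials@data, .lagDesign, P = order)
  K <- ncol(posterior@gamma[[1L]])
  counts <- matrix(0, K, K)
  for (x in posterior@xi)                       # (T-1) x K x K slices
    if (length(x)) counts <- counts + apply(x, c(2L, 3L), sum)
  .mStepCore(designs, posterior@gamma, counts, order, u,
             epsQ = 1e-6 * mean(vapply(trials@data, function(m)
               mean(apply(m, 1L, var)), 1)),
             prev = prev, diagQ = diagQ)
}

# Core M-step. gammas: per-trial T x K. transCounts: K x K summed
# pairwise marginals. epsQ: ridge added to covariance estimates.
.mStepCore <- function(designs, gammas, transCounts, P, u, epsQ,
                       prev = NULL, diagQ = FALSE) {
  K <- ncol(gammas[[1L]])
  D <- ncol(designs[[1L]]$Y)
  p1 <- P * D + 1L
  Z <- do.call(rbind, lapply(designs, `[[`, "Z"))
  Y <- do.call(rbind, lapply(designs, `[[`, "Y"))
  G <- do.call(rbind, lapply(seq_along(designs), function(i) {
    Ti <- nrow(gammas[[i]])
    gammas[[i]][(P + 1L):Ti, , drop = FALSE]
  }))
  A <- array(0, c(K, P, D, D))
  Q <- array(0, c(K, D, D))
  mu <- matrix(0, K, D)
  minResp <- P * D + D + 1
  for (z in seq_len(K)) {
    w <- G[, z]
    tot <- sum(w)
    if (tot < minResp && !is.null(prev)) {
      # state collapse: keep previous dynamics, reseed the bias near the
      # global mean to give the state a chance to reacquire data
      warning(sprintf(
        "state %d collapsed (total responsibility %.2f); reseeding bias",
        z, tot))
      A[z, , , ] <- prev@A[z, , , ]
      Q[z, , ] <- prev@Q[z, , ]
      gm <- colMeans(Y)
      mu[z, ] <- gm + stats::rnorm(D, 0, 0.1 * pmax(apply(Y, 2L, sd), 1e-8))
      next
    }
    Zw <- Z * w
    ZtZ <- crossprod(Zw, Z)
    ZtY <- crossprod(Zw, Y)
    B <- tryCatch(solve(ZtZ, ZtY), error = function(e)
      solve(ZtZ + diag(1e-8 * max(diag(ZtZ)), p1), ZtY))
    E <- Y - Z %*% B
    Qz <- crossprod(E * w, E) / tot
    if (diagQ) Qz <- diag(diag(Qz), D)
    # ridge guards low-responsibility states; a single state pools every
    # sample and stays exactly the OLS residual covariance
    Qz <- (Qz + t(Qz)) / 2 + diag(if (K > 1L) epsQ else 0, D)
    un <- .unpackB(B, P, D)
    A[z, , , ] <- un$A
    mu[z, ] <- un$mu
    Q[z, , ] <- Qz
  }
  rs <- rowSums(transCounts)
  trans <- transCounts / ifelse(rs > 0, rs, 1)
  trans[rs == 0, ] <- 1 / K
  trans <- smoothTransitions(trans, u)
  initDist <- colSums(do.call(rbind, lapply(gammas, function(g)
    g[1L, , drop = FALSE])))
  initDist <- pmax(initDist, 1e-12)
  initDist <- initDist / sum(initDist)
  new("ARHMMParams", A = A, Q = Q, mu = mu, trans = trans,
      initDist = initDist)
}

#' Fit an ARHMM by Baum-Welch expectation-maximization
#'
#' Alternates exact forward-backward smoothing (E-step) with the sticky
#' weighted-regression M-step until the relative log-likelihood change
#' falls below `tol`. Trials are independent sequences sharing one
#' parameter set. Multiple restarts jitter the initialization; the
#' restart with the best final log-likelihood wins.
#'
#' @param trials a [TrialTensor-class].
#' @param init an [ARHMMParams-class] initialization (e.g., from
#'   [initialParams()]).
#' @param maxIter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance
#'   (default 1e-6).
#' @param nRestarts number of restarts; the first uses `init` verbatim,
#'   later ones jitter it (default 3).
#' @param seed integer seed for the restart jitter (optional).
#' @param stickiness self-transition pseudocount weight `u`
#'   (default 0.5).
#' @param estimateInitDist estimate the initial distribution (default);
#'   `FALSE` fixes it uniform.
#' @param diagQ constrain innovation covariances to diagonal.
#' @return an [ARHMMFit-class].
#' @export
fitARHMM <- function(trials, init, maxIter = 200L, tol = 1e-6,
                     nRestarts = 3L, seed = NULL, stickiness = 0.5,
                     estimateInitDist = TRUE, diagQ = FALSE) {
  stopifnot(is(trials, "TrialTensor"), is(init, "ARHMMParams"))
  P <- arOrder(init)
  designs <- lapply(trials@data, .lagDesign, P = P)
  Tlens <- nSamples(trials)
  if (any(Tlens <= P)) stop("every trial must be longer than the AR order")
  datasd <- mean(vapply(trials@data, function(m) mean(apply(m, 1L, sd)), 1))
  epsQ <- 1e-6 * datasd^2

  runOne <- function(start) {
    params <- start
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    post <- NULL
    for (it in seq_len(maxIter)) {
      post <- .eStep(params, designs, Tlens)
      trace <- c(trace, post$loglik)
      if (is.finite(prev)) {
        dec <- prev - post$loglik
        if (dec > 1e-8 * abs(prev) + 1e-10)
          warning(sprintf(
            "EM log-likelihood decreased at iteration %d by %.3g", it, dec))
        if (abs(post$loglik - prev) < tol * abs(prev)) {
          converged <- TRUE
          break
        }
      }
      prev <- post$loglik
      counts <- matrix(0, nStates(params), nStates(params))
      for (x in post$xi)                        # K x K x (T-1) cubes
        if (length(x)) counts <- counts + apply(x, c(1L, 2L), sum)
      newp <- .mStepCore(designs, post$gamma, counts, P, stickiness,
                         epsQ, prev = params, diagQ = diagQ)
      if (!estimateInitDist)
        newp@initDist <- rep(1 / nStates(init), nStates(init))
      params <- newp
    }
    list(params = params, post = post, trace = trace,
         converged = converged, niter = length(trace))
  }

  jitter <- function(start, r) {
    p <- start
    p@mu <- p@mu + matrix(stats::rnorm(length(p@mu), 0, 0.05 * datasd),
                          nrow(p@mu))
    p@A <- p@A + array(stats::rnorm(length(p@A), 0, 0.02), dim(p@A))
    p
  }

  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      start <- if (r == 1L) init else jitter(init, r)
      run <- runOne(start)
      if (is.null(best) || run$post$loglik > best$post$loglik) best <- run
    }
  })

  K <- nStates(init)
  xi <- lapply(best$post$xi, function(x)
    if (length(x)) aperm(x, c(3L, 1L, 2L)) else array(0, c(0L, K, K)))
  new("ARHMMFit", params = best$params,
      posterior = new("StatePosterior", gamma = best$post$gamma,
                      xi = xi, loglik = best$post$loglik),
      loglikTrace = best$trace, converged = best$converged,
      niter = as.integer(best$niter))
}

#' Most likely state sequence (Viterbi decoding)
#'
#' @param params an [ARHMMParams-class].
#' @param x a `channels x samples` matrix or a [TrialTensor-class] with
#'   `trial`.
#' @param trial trial index when `x` is a `TrialTensor`.
#' @return integer state path of length `T`; exact ties break toward the
#'   lower state index.
#' @export
viterbiPath <- function(params, x, trial = 1L) {
  if (is(x, "TrialTensor")) x <- trialData(x, trial)
  logB <- emissionLoglik(params, x)
  lt <- log(params@trans)
  li <- log(params@initDist)
  as.integer(viterbi_cpp(logB, lt, li))
}

#' Bayesian information criterion of a fitted ARHMM
#'
#' `BIC = -2 loglik + P log N` with parameter count
#' `P = K (order D^2 + D + D(D+1)/2) + K(K-1) + (K-1)` and `N` the total
#' number of regressed samples, `sum_trials (T - order)`.
#'
#' @param fit an [ARHMMFit-class] (or anything with `totalLogLik`),
#'   or a numeric log-likelihood.
#' @param trials the [TrialTensor-class] the likelihood was computed on.
#' @param params optional [ARHMMParams-class] when `fit` is numeric.
#' @return the BIC value (smaller is better).
#' @export
bicARHMM <- function(fit, trials, params = NULL) {
  if (is.numeric(fit)) {
    ll <- fit
    stopifnot(!is.null(params))
  } else {
    ll <- totalLogLik(fit)
    params <- fittedParams(fit)
  }
  K <- nStates(params); D <- nChannels(params); P <- arOrder(params)
  npar <- K * (P * D^2 + D + D * (D + 1) / 2) + K * (K - 1) + (K - 1)
  N <- sum(nSamples(trials) - P)
  -2 * ll + npar * log(N)
}

# Log-likelihood of fixed parameters on a set of trials (one E-step
# forward pass, no updates).
.loglikOn <- function(params, trials) {
  designs <- lapply(trials@data, .lagDesign, P = arOrder(params))
  .eStep(params, designs, nSamples(trials))$loglik
}

#' Sweep model dimensions and score by BIC and held-out likelihood
#'
#' For every combination of state count and AR order: initialize from
#' windowed-MVAR clustering on the training trials, fit by EM, and report
#' the BIC on all trials plus the mean per-sample log-likelihood on the
#' held-out trials.
#'
#' @param trials a [TrialTensor-class].
#' @param kRange integer vector of state counts.
#' @param orderRange integer vector of AR orders.
#' @param heldoutFraction fraction of trials held out (default 0.2).
#' @param seed integer seed controlling the split, clustering and EM
#'   restarts.
#' @param winLen,winStep AMVAR window length and step in seconds used for
#'   initialization (defaults 0.1 and 0.05).
#' @param nRestarts EM restarts per fit (default 1 for sweep speed).
#' @param ... further arguments to [fitARHMM()].
#' @return list with `table` (data.frame: `k`, `order`, `loglik`, `bic`,
#'   `heldout_loglik_per_sample`), `bestK`, `bestOrder` (argmin BIC).
#' @export
selectModel <- function(trials, kRange, orderRange, heldoutFraction = 0.2,
                        seed = 1L, winLen = 0.1, winStep = 0.05,
                        nRestarts = 1L, ...) {
  stopifnot(length(kRange) >= 1L, length(orderRange) >= 1L)
  n <- nTrials(trials)
  nHeld <- round(heldoutFraction * n)
  if (nHeld < 2L || n - nHeld < 2L)
    stop("held-out split leaves fewer than 2 trials on one side")
  held <- .withSeed(deriveSeed(seed, "heldout"),
                    sort(sample.int(n, nHeld)))
  train <- trials[setdiff(seq_len(n), held)]
  heldT <- trials[held]
  rows <- list()
  for (P in orderRange) for (K in kRange) {
    init <- amvarInit(train, k = K, order = P, winLen = winLen,
                      winStep = winStep,
                      seed = deriveSeed(seed, sprintf("init%d_%d", K, P)))
    fit <- fitARHMM(train, init, nRestarts = nRestarts,
                    seed = deriveSeed(seed, sprintf("fit%d_%d", K, P)), ...)
    llAll <- .loglikOn(fittedParams(fit), trials)
    llHeld <- .loglikOn(fittedParams(fit), heldT)
    rows[[length(rows) + 1L]] <- data.frame(
      k = K, order = P, loglik = llAll,
      bic = bicARHMM(llAll, trials, fittedParams(fit)),
      heldout_loglik_per_sample = llHeld / sum(nSamples(heldT) - P))
  }
  tab <- do.call(rbind, rows)
  best <- tab[which.min(tab$bic), ]
  list(table = tab, bestK = best$k, bestOrder = best$order)
}
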