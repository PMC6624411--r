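# Independent oracles used across the suite. These deliberately avoid the
# package's own recursions: posteriors and Viterbi paths by exhaustive
# enumeration over all K^T state paths, Gaussian densities by the direct
# determinant/solve formula.

# Exhaustive path-sum smoothing: returns gamma (T x K), xi ((T-1) x K x K),
# loglik, and the maximum-probability path (first one in lexicographic
# order on ties, matching lowest-index tie-breaking).
bruteForceHMM <- function(logB, trans, initDist) {
  T <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))[, T:1, drop = FALSE]
  logp <- apply(paths, 1L, function(z) {
    lp <- log(initDist[z[1L]]) + logB[1L, z[1L]]
    if (T > 1L) for (t in 2L:T)
      lp <- lp + log(trans[z[t - 1L], z[t]]) + logB[t, z[t]]
    lp
  })
  M <- max(logp)
  w <- exp(logp - M)
  loglik <- M + log(sum(w))
  w <- w / sum(w)
  gamma <- matrix(0, T, K)
  for (t in seq_len(T)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k])
  xi <- array(0, c(max(T - 1L, 0L), K, K))
  if (T > 1L) for (t in seq_len(T - 1L)) for (i in seq_len(K)) for (j in seq_len(K))
    xi[t, i, j] <- sum(w[paths[, t] == i & paths[, t + 1L] == j])
  # lexicographically-first argmax ~ ties toward lower state indices
  best <- which(logp >= max(logp) - 1e-12)
  ord <- do.call(order, as.data.frame(paths[best, , drop = FALSE]))
  list(gamma = gamma, xi = xi, loglik = loglik,
       viterbi = as.integer(paths[best[ord[1L]], ]))
}

# Direct multivariate normal log-density (determinant + solve; no
# Cholesky shortcut shared with the implementation).
dmvnormLog <- function(x, mean, Sigma) {
  d <- length(x)
  -0.5 * (d * log(2 * pi) + log(det(Sigma)) +
            as.numeric(t(x - mean) %*% solve(Sigma, x - mean)))
}

# Small random valid ARHMM parameters (stable states).
randomParams <- function(K, D, P, seed) {
  withr::with_seed(seed, {
    A <- array(0, c(K, P, D, D))
    for (z in seq_len(K)) {
      repeat {
        cand <- array(rnorm(P * D * D, 0, 0.3), c(P, D, D))
        if (spectralRadius(cand) < 0.95) break
      }
      A[z, , , ] <- cand
    }
    Q <- array(0, c(K, D, D))
    for (z in seq_len(K)) {
      R <- matrix(rnorm(D * D, 0, 0.3), D, D)
      Q[z, , ] <- crossprod(R) + diag(0.2, D)
    }
    mu <- matrix(rnorm(K * D, 0, 0.5), K, D)
    trans <- matrix(rgamma(K * K, 2), K, K) + diag(3, K)
    trans <- trans / rowSums(trans)
    initDist <- rep(1 / K, K)
    ARHMMParams(A, Q, mu = mu, trans = trans, initDist = initDist)
  })
}

# Quick simulated dataset at the robustness-study design scale.
quickSim <- function(seed, nTrials = 30L, trialLength = 400L, snr = 30,
                     nStates = 3L, nChannels = 6L, arOrder = 2L, ...) {
  cfg <- simConfig(nStates = nStates, nChannels = nChannels,
                   arOrder = arOrder, nTrials = nTrials,
                   trialLength = trialLength, snr = snr, seed = seed, ...)
  sim <- simulateDataset(makeGroundTruthParams(cfg), cfg)
  sim$config <- cfg
  sim
}

# Build a pair of length-n vectors with Pearson correlation exactly r.
exactCorPair <- function(r, n, seed = 1) {
  withr::with_seed(seed, {
    x <- scale(rnorm(n))[, 1]
    u <- rnorm(n)
    u <- u - x * sum(u * x) / sum(x * x)   # orthogonal to x
    u <- u - mean(u)
    u <- u - x * sum(u * x) / sum(x * x)
    u <- u / sd(u)
    list(x = x, y = r * x + sqrt(1 - r^2) * u)
  })
}
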