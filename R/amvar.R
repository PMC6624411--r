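# Windowed adaptive MVAR estimation and k-means clustering of the
# window-wise dynamics, used to initialize the ARHMM. Windows pool
# samples across trials at fixed latency -- exactly the "states occur at
# the same times across all trials" assumption the ARHMM later relaxes,
# kept here for initialization fidelity.

#' Windowed (adaptive) MVAR estimation
#'
#' Slides uniform windows over the trial timeline; in each window, pools
#' the samples of all trials at those latencies and solves the
#' multivariate least-squares regression of `x_t` on its `order` lags and
#' an intercept. Lagged predictors may reach before the window start (but
#' never outside the trial).
#'
#' @param trials a [TrialTensor-class] with equal-length trials.
#' @param winLen window length in seconds (default 0.1, i.e. 100 ms).
#' @param winStep window step in seconds (default 0.05, i.e. 50 ms
#'   overlap for the default length).
#' @param order AR order (default 2).
#' @return a [WindowedMVAR-class].
#' @export
fitWindowMVAR <- function(trials, winLen = 0.1, winStep = 0.05,
                          order = 2L) {
  stopifnot(is(trials, "TrialTensor"))
  Ts <- nSamples(trials)
  if (length(unique(Ts)) != 1L)
    stop("windowed MVAR requires equal-length trials")
  T <- Ts[1L]; D <- nChannels(trials); rate <- samplingRate(trials)
  wl <- max(1L, round(winLen * rate))
  ws <- max(1L, round(winStep * rate))
  starts <- seq(1L, T - wl + 1L, by = ws)
  W <- length(starts)
  need <- order * D + D + 1
  if (wl * nTrials(trials) <= need)
    stop("windows too short for the regression support: need more than ",
         need, " pooled samples per window")
  coeffs <- array(0, c(W, order, D, D))
  noiseCov <- array(0, c(W, D, D))
  bias <- matrix(0, W, D)
  designs <- lapply(trials@data, .lagDesign, P = order)
  for (w in seq_len(W)) {
    # regression targets: samples in the window with a full lag history
    rows <- starts[w]:(starts[w] + wl - 1L)
    rows <- rows[rows > order] - order        # row index into design
    if (length(rows) == 0L)
      stop("window ", w, " has no samples with a full lag history")
    Z <- do.call(rbind, lapply(designs, function(d)
      d$Z[rows, , drop = FALSE]))
    Y <- do.call(rbind, lapply(designs, function(d)
      d$Y[rows, , drop = FALSE]))
    B <- tryCatch(qr.solve(Z, Y), error = function(e)
      stop("rank-deficient design in window ", w))
    E <- Y - Z %*% B
    un <- .unpackB(B, order, D)
    coeffs[w, , , ] <- un$A
    bias[w, ] <- un$mu
    S <- crossprod(E) / nrow(E)
    noiseCov[w, , ] <- (S + t(S)) / 2
  }
  wins <- cbind((starts - 1L) / rate, (starts - 1L + wl) / rate)
  new("WindowedMVAR", windows = wins, coeffs = coeffs,
      noiseCov = noiseCov, bias = bias, order = as.integer(order))
}

#' Cluster windowed MVAR estimates into candidate states
#'
#' k-means (Euclidean distance, k-means++-style default seeding of
#' [stats::kmeans()], 10 restarts, best inertia kept) on the flattened
#' per-window coefficient tensors, optionally concatenated with the
#' vectorized residual covariances.
#'
#' @param wmvar a [WindowedMVAR-class].
#' @param k number of clusters.
#' @param seed integer seed.
#' @param includeCov append the vectorized noise covariance to the
#'   feature vector (default `FALSE`: coefficients only).
#' @param nRestarts k-means restarts (default 10).
#' @return list with `labels` (per window) and `centroids`
#'   (`k x features`).
#' @export
clusterWindows <- function(wmvar, k, seed = 1L, includeCov = FALSE,
                           nRestarts = 10L) {
  stopifnot(is(wmvar, "WindowedMVAR"))
  W <- dim(wmvar@coeffs)[1L]
  if (k > W) stop("k must not exceed the number of windows")
  feat <- matrix(wmvar@coeffs, W)
  if (includeCov) feat <- cbind(feat, matrix(wmvar@noiseCov, W))
  if (k == 1L)
    return(list(labels = rep(1L, W),
                centroids = matrix(colMeans(feat), 1L)))
  km <- .withSeed(seed,
                  stats::kmeans(feat, centers = k, nstart = nRestarts,
                                iter.max = 100L))
  list(labels = as.integer(km$cluster), centroids = km$centers)
}

#' ARHMM initialization from clustered window dynamics
#'
#' Refits each cluster's AR coefficients, bias and residual covariance by
#' least squares pooled over that cluster's windows; initializes the
#' transition matrix from the empirical window-label transitions smoothed
#' by the sticky self-transition prior; and perturbs the state biases
#' with a small seeded jitter (std 1% of the data std) to break symmetry.
#'
#' @param wmvar the [WindowedMVAR-class] behind `labels`.
#' @param labels per-window cluster labels from [clusterWindows()].
#' @param trials the [TrialTensor-class] the windows were fit on.
#' @param order AR order (default: the window order).
#' @param u stickiness for the transition smoothing (default 0.5).
#' @param seed integer seed for the bias jitter.
#' @return an [ARHMMParams-class].
#' @export
initialParams <- function(wmvar, labels, trials, order = NULL, u = 0.5,
                          seed = 1L) {
  stopifnot(is(wmvar, "WindowedMVAR"), is(trials, "TrialTensor"))
  if (is.null(order)) order <- wmvar@order
  K <- max(labels)
  D <- nChannels(trials)
  rate <- samplingRate(trials)
  T <- nSamples(trials)[1L]
  designs <- lapply(trials@data, .lagDesign, P = order)
  wl <- round((wmvar@windows[1L, 2L] - wmvar@windows[1L, 1L]) * rate)
  A <- array(0, c(K, order, D, D))
  Q <- array(0, c(K, D, D))
  mu <- matrix(0, K, D)
  minRows <- order * D + D + 1
  rowsOf <- function(w) {
    start <- round(wmvar@windows[w, 1L] * rate) + 1L
    r <- start:(start + wl - 1L)
    r <- r[r > order & r <= T] - order
    r
  }
  pooledRows <- lapply(seq_len(K), function(z)
    sort(unique(unlist(lapply(which(labels == z), rowsOf)))))
  # clusters with too little regression support merge into the nearest
  # (most common neighboring) cluster
  for (z in seq_len(K))
    if (length(pooledRows[[z]]) * nTrials(trials) < minRows) {
      warning("cluster ", z, " has too few samples; merging")
      donor <- which.max(vapply(pooledRows, length, 1L))
      pooledRows[[z]] <- pooledRows[[donor]]
    }
  for (z in seq_len(K)) {
    rows <- pooledRows[[z]]
    Z <- do.call(rbind, lapply(designs, function(d)
      d$Z[rows, , drop = FALSE]))
    Y <- do.call(rbind, lapply(designs, function(d)
      d$Y[rows, , drop = FALSE]))
    B <- qr.solve(Z, Y)
    E <- Y - Z %*% B
    un <- .unpackB(B, order, D)
    A[z, , , ] <- un$A
    mu[z, ] <- un$mu
    S <- crossprod(E) / nrow(E)
    Q[z, , ] <- (S + t(S)) / 2 + diag(1e-8 + 1e-6 * mean(diag(S)), D)
  }
  counts <- matrix(0, K, K)
  for (w in seq_len(length(labels) - 1L))
    counts[labels[w], labels[w + 1L]] <-
      counts[labels[w], labels[w + 1L]] + 1
  counts <- counts + 1e-3                      # keep rows proper
  trans <- smoothTransitions(counts / rowSums(counts), u)
  datasd <- mean(vapply(trials@data, function(m) mean(apply(m, 1L, sd)), 1))
  mu <- mu + .withSeed(seed,
                       matrix(stats::rnorm(K * D, 0, 0.01 * datasd), K, D))
  initDist <- rep(1 / K, K)
  new("ARHMMParams", A = A, Q = Q, mu = mu, trans = trans,
      initDist = initDist)
}

#' One-call AMVAR initialization
#'
#' Convenience wrapper: [fitWindowMVAR()] then [clusterWindows()] then
#' [initialParams()].
#'
#' @param trials a [TrialTensor-class].
#' @param k number of states.
#' @param order AR order (default 2).
#' @param winLen,winStep window geometry in seconds (defaults 0.1/0.05).
#' @param u stickiness (default 0.5).
#' @param seed integer seed.
#' @param includeCov cluster on coefficients plus covariances.
#' @return an [ARHMMParams-class].
#' @export
amvarInit <- function(trials, k, order = 2L, winLen = 0.1,
                      winStep = 0.05, u = 0.5, seed = 1L,
                      includeCov = FALSE) {
  wm <- fitWindowMVAR(trials, winLen = winLen, winStep = winStep,
                      order = order)
  cl <- clusterWindows(wm, k = k, seed = deriveSeed(seed, "kmeans"),
                       includeCov = includeCov)
  initialParams(wm, cl$labels, trials, order = order, u = u,
                seed = deriveSeed(seed, "jitter"))
}
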