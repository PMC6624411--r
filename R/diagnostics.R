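# Model-adequacy diagnostics: one-step-ahead residuals under the fitted
# switching-AR model and their lagged auto-/cross-correlations (residual
# whiteness test).

#' Residuals of a fitted ARHMM
#'
#' One-step-ahead prediction residuals `x_t - (sum_tau A_z tau x_{t-tau}
#' + mu_z)`, with the predicting state taken from the Viterbi path
#' (`mode = "viterbi"`, default) or as the responsibility-weighted mixture
#' of all states' predictions (`mode = "soft"`). The first `order`
#' samples of each trial are dropped.
#'
#' @param fit an [ARHMMFit-class].
#' @param trials the [TrialTensor-class] the model was fit on.
#' @param mode `"viterbi"` or `"soft"`.
#' @return a [TrialTensor-class] of residuals (`T - order` samples per
#'   trial).
#' @export
modelResiduals <- function(fit, trials, mode = c("viterbi", "soft")) {
  mode <- match.arg(mode)
  stopifnot(is(fit, "ARHMMFit"), is(trials, "TrialTensor"))
  params <- fittedParams(fit)
  P <- arOrder(params); K <- nStates(params)
  res <- vector("list", nTrials(trials))
  for (i in seq_len(nTrials(trials))) {
    X <- trialData(trials, i)
    des <- .lagDesign(X, P)
    preds <- lapply(seq_len(K), function(z)
      des$Z %*% .packB(arCoefficients(params, z), stateBias(params, z)))
    if (mode == "viterbi") {
      zhat <- viterbiPath(params, X)[(P + 1L):ncol(X)]
      pred <- matrix(0, nrow(des$Y), ncol(des$Y))
      for (z in seq_len(K)) {
        rows <- zhat == z
        pred[rows, ] <- preds[[z]][rows, , drop = FALSE]
      }
    } else {
      g <- fit@posterior@gamma[[i]][(P + 1L):ncol(X), , drop = FALSE]
      pred <- Reduce(`+`, lapply(seq_len(K), function(z)
        preds[[z]] * g[, z]))
    }
    res[[i]] <- t(des$Y - pred)
  }
  # event markers are not meaningful on the shortened residual trials
  TrialTensor(res, rate = samplingRate(trials),
              channelLabels = channelLabels(trials))
}

#' Residual whiteness test
#'
#' Pools residuals across trials and computes, for each lag `1..maxLag`
#' (lag zero excluded), the `D x D` matrix of lagged auto- and
#' cross-correlations. If the model captures the temporal structure, all
#' entries should be near zero; the test passes when at least 95% of
#' entries fall below the threshold (default `3 / sqrt(N)`, the
#' three-sigma band of a white-noise correlation estimate on `N` pooled
#' samples).
#'
#' @param residuals a [TrialTensor-class] of residuals from
#'   [modelResiduals()].
#' @param maxLag largest lag, typically the AR order (default 1).
#' @param threshold pass threshold on `|corr|`; default `3/sqrt(N)`.
#' @return a [WhitenessReport-class].
#' @export
whitenessTest <- function(residuals, maxLag = 1L, threshold = NULL) {
  stopifnot(is(residuals, "TrialTensor"), maxLag >= 1L)
  D <- nChannels(residuals)
  centered <- lapply(residuals@data, function(X) X - rowMeans(X))
  sds <- sqrt(rowSums(do.call(cbind, centered)^2))
  drop <- sds < 1e-12
  if (any(drop)) {
    warning("excluding zero-variance residual channel(s): ",
            paste(which(drop), collapse = ", "))
    centered <- lapply(centered, function(X) X[!drop, , drop = FALSE])
    sds <- sds[!drop]
    D <- sum(!drop)
  }
  N <- sum(vapply(centered, ncol, 1L))
  if (is.null(threshold)) threshold <- 3 / sqrt(N)
  corr <- array(0, c(maxLag, D, D))
  for (l in seq_len(maxLag)) {
    S <- matrix(0, D, D)
    for (X in centered) {
      T <- ncol(X)
      if (T > l)
        S <- S + X[, (l + 1L):T, drop = FALSE] %*%
          t(X[, 1L:(T - l), drop = FALSE])
    }
    corr[l, , ] <- S / (sds %o% sds)
  }
  maxAbs <- max(abs(corr))
  passFrac <- mean(abs(corr) < threshold)
  new("WhitenessReport", lags = seq_len(maxLag), corr = corr,
      maxAbs = maxAbs, threshold = threshold, passFrac = passFrac,
      pass = passFrac >= 0.95, n = as.integer(N))
}
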