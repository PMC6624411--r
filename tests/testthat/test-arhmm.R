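test_that("emission log-likelihood reduces to iid and matches the dense oracle", {
  # D = 1, A = 0, mu = 0, Q = 1: standard normal density
  p <- ARHMMParams(array(0, c(1, 1, 1, 1)), array(1, c(1, 1, 1)),
                   trans = matrix(1), initDist = 1)
  x <- matrix(c(0.3, -1.2, 0.5, 2), 1)
  lb <- emissionLoglik(p, x)
  expect_equal(lb[1, 1], 0)                       # conditioned-on sample
  expect_equal(lb[2:4, 1], dnorm(x[1, 2:4], log = TRUE))

  # two identical states give equal columns
  p2 <- randomParams(1, 3, 2, seed = 41)
  A2 <- array(0, c(2, 2, 3, 3)); A2[1, , , ] <- A2[2, , , ] <- p2@A[1, , , ]
  Q2 <- array(0, c(2, 3, 3)); Q2[1, , ] <- Q2[2, , ] <- p2@Q[1, , ]
  twin <- ARHMMParams(A2, Q2, mu = rbind(p2@mu, p2@mu))
  X <- withr::with_seed(42, matrix(rnorm(3 * 8), 3, 8))
  lb2 <- emissionLoglik(twin, X)
  expect_equal(lb2[, 1], lb2[, 2])

  # random instance against the direct multivariate-normal oracle
  p3 <- randomParams(2, 3, 2, seed = 43)
  lb3 <- emissionLoglik(p3, X)
  for (t in 3:8) for (z in 1:2) {
    A <- arCoefficients(p3, z)
    m <- stateBias(p3, z)
    for (tau in 1:2) m <- m + matrix(A[tau, , ], 3, 3) %*% X[, t - tau]
    expect_equal(lb3[t, z], dmvnormLog(X[, t], m, noiseCovariance(p3, z)),
                 tolerance = 1e-12)
  }
})

test_that("forward-backward matches exhaustive enumeration (T<=8, K<=3)", {
  for (seed in 1:6) {
    K <- 1 + seed %% 3
    T <- 5 + seed %% 4
    withr::with_seed(100 + seed, {
      logB <- matrix(rnorm(T * K), T, K)
      trans <- matrix(rgamma(K * K, 2), K, K); trans <- trans / rowSums(trans)
      init <- rgamma(K, 2); init <- init / sum(init)
    })
    bf <- bruteForceHMM(logB, trans, init)
    fb <- forwardBackward(logB, trans, init)
    expect_lt(max(abs(responsibilities(fb, 1) - bf$gamma)), 1e-10)
    expect_lt(max(abs(pairwiseMarginals(fb, 1) - bf$xi)), 1e-10)
    expect_equal(totalLogLik(fb), bf$loglik, tolerance = 1e-12)
    # Viterbi agrees with the exhaustive argmax
    vp <- netstates:::viterbi_cpp(logB, log(trans), log(init))
    expect_equal(as.integer(vp), bf$viterbi)
  }
})

test_that("forward-backward degenerate cases behave as the chain prior dictates", {
  # K = 1: gamma all ones, loglik the sum of emissions
  logB <- matrix(c(-1, -2, -0.5), 3, 1)
  fb <- forwardBackward(logB, matrix(1), 1)
  expect_equal(responsibilities(fb, 1), matrix(1, 3, 1))
  expect_equal(totalLogLik(fb), sum(logB))
  # uniform emissions, uniform chain: gamma uniform
  fb2 <- forwardBackward(matrix(0, 5, 2), matrix(0.5, 2, 2), c(0.5, 0.5))
  expect_equal(responsibilities(fb2, 1), matrix(0.5, 5, 2))
  # no underflow on long sequences
  fb3 <- forwardBackward(matrix(-50, 1e5, 2), matrix(0.5, 2, 2),
                         c(0.5, 0.5))
  expect_true(is.finite(totalLogLik(fb3)))
  expect_error(forwardBackward(matrix(-Inf, 3, 2), matrix(0.5, 2, 2),
                               c(0.5, 0.5)), "impossible")
})

test_that("posterior marginals are exactly normalized and consistent", {
  for (seed in 1:5) {
    sim <- quickSim(seed = 300 + seed, nTrials = 3, trialLength = 150,
                    snr = 3)
    p <- truthParams(sim$truth)
    logB <- emissionLoglik(p, sim$observed, trial = 1)
    fb <- forwardBackward(logB, transitionMatrix(p),
                          initialDistribution(p))
    g <- responsibilities(fb, 1)
    xi <- pairwiseMarginals(fb, 1)
    expect_lt(max(abs(rowSums(g) - 1)), 1e-12)
    expect_lt(max(abs(apply(xi, 1, sum) - 1)), 1e-12)
    # marginalizing xi reproduces the adjacent gammas
    expect_lt(max(abs(apply(xi, c(1, 2), sum) -
                        g[-nrow(g), , drop = FALSE])), 1e-9)
    expect_lt(max(abs(apply(xi, c(1, 3), sum) -
                        g[-1, , drop = FALSE])), 1e-9)
  }
})

test_that("transition smoothing obeys its contract", {
  # fixed point of the identity
  expect_equal(smoothTransitions(diag(2), 0.7), diag(2))
  # the printed 2x2 uniform example
  expect_equal(smoothTransitions(matrix(0.5, 2, 2), 0.5),
               matrix(c(2, 1, 1, 2) / 3, 2))
  # u = 0 is the identity map
  M <- matrix(c(0.3, 0.6, 0.7, 0.4), 2)
  expect_identical(smoothTransitions(M, 0), M)
  # row-stochastic in, row-stochastic out with floored diagonal
  for (u in c(0.1, 0.5, 2)) {
    S <- smoothTransitions(M, u)
    expect_equal(rowSums(S), c(1, 1))
    expect_true(all(diag(S) >= u / (1 + u)))
  }
})

test_that("the M-step recovers weighted OLS and smoothed transitions", {
  sim <- quickSim(seed = 51, nTrials = 15, trialLength = 300, snr = Inf)
  p <- truthParams(sim$truth)
  designs <- lapply(sim$observed@data, netstates:::.lagDesign, P = 2L)
  post <- netstates:::.eStep(p, designs, nSamples(sim$observed))
  sp <- new("StatePosterior", gamma = post$gamma,
            xi = lapply(post$xi, function(x) aperm(x, c(3, 1, 2))),
            loglik = post$loglik)
  up <- mStep(sim$observed, sp, order = 2L, u = 0.5)
  expect_equal(rowSums(transitionMatrix(up)), rep(1, 3))
  expect_true(all(diag(transitionMatrix(up)) >= 0.5 / 1.5))
  expect_equal(sum(initialDistribution(up)), 1)
  # near-true posteriors should reproduce dynamics close to the truth
  for (z in 1:3)
    expect_lt(max(abs(arCoefficients(up, z) - arCoefficients(p, z))), 0.2)
})

test_that("a single-state EM fit equals the pooled OLS estimate", {
  sim <- quickSim(seed = 52, nTrials = 10, trialLength = 150, nStates = 1,
                  nChannels = 3, snr = Inf, scheduleMode = "fixed_blocks",
                  meanNoiseGain = 0)
  init <- amvarInit(sim$observed, k = 1, order = 2, seed = 1)
  fit <- fitARHMM(sim$observed, init, nRestarts = 1, seed = 1)
  expect_lte(fit@niter, 3)
  des <- lapply(sim$observed@data, netstates:::.lagDesign, P = 2L)
  Z <- do.call(rbind, lapply(des, `[[`, "Z"))
  Y <- do.call(rbind, lapply(des, `[[`, "Y"))
  B <- qr.solve(Z, Y)
  ref <- netstates:::.unpackB(B, 2L, 3L)
  E <- Y - Z %*% B
  Qref <- crossprod(E) / nrow(E)
  expect_equal(arCoefficients(fittedParams(fit), 1), ref$A,
               tolerance = 1e-8)
  expect_equal(stateBias(fittedParams(fit), 1), ref$mu, tolerance = 1e-8)
  expect_equal(noiseCovariance(fittedParams(fit), 1), Qref,
               tolerance = 1e-6)
})

test_that("EM increases the likelihood and recovers well-separated states", {
  sim <- quickSim(seed = 53, nTrials = 30, trialLength = 400, snr = 30)
  init <- amvarInit(sim$observed, k = 3, order = 2, seed = 2)
  fit <- fitARHMM(sim$observed, init, nRestarts = 1, seed = 2)
  tr <- loglikTrace(fit)
  expect_true(all(diff(tr) > -1e-8 * abs(tr[-length(tr)])))
  ras <- stateRaster(fit, sim$observed)
  m <- matchStates(ras@states, truthRaster(sim$truth), k = 3)
  expect_gte(m$accuracy, 0.95)
})

test_that("Viterbi decoding follows dominated likelihoods and breaks ties low", {
  # emissions overwhelmingly favoring one state per segment
  K <- 3
  logB <- rbind(matrix(rep(c(0, -50, -50), 4), 4, 3, byrow = TRUE),
                matrix(rep(c(-50, 0, -50), 4), 4, 3, byrow = TRUE))
  path <- netstates:::viterbi_cpp(logB, log(matrix(1 / 3, 3, 3)),
                                  log(rep(1 / 3, 3)))
  expect_equal(as.integer(path), rep(1:2, each = 4))
  # fully tied problem decodes to the lowest state index
  tied <- netstates:::viterbi_cpp(matrix(0, 5, 3),
                                  log(matrix(1 / 3, 3, 3)),
                                  log(rep(1 / 3, 3)))
  expect_equal(as.integer(tied), rep(1L, 5))
})

test_that("BIC follows the closed form and penalizes duplicated states", {
  trials <- TrialTensor(list(matrix(rnorm(101), 1, 101)), rate = 10)
  p1 <- ARHMMParams(array(0.1, c(1, 1, 1, 1)), array(1, c(1, 1, 1)))
  expect_equal(bicARHMM(-100, trials, p1), 200 + 3 * log(100))
  # duplicating a state cannot raise the likelihood but raises the penalty
  sim <- quickSim(seed = 54, nTrials = 6, trialLength = 150, nStates = 2,
                  nChannels = 2, snr = Inf)
  p <- truthParams(sim$truth)
  ll2 <- netstates:::.loglikOn(p, sim$observed)
  A3 <- array(0, c(3, 2, 2, 2)); Q3 <- array(0, c(3, 2, 2))
  A3[1:2, , , ] <- p@A; A3[3, , , ] <- p@A[2, , , ]
  Q3[1:2, , ] <- p@Q; Q3[3, , ] <- p@Q[2, , ]
  dup <- ARHMMParams(A3, Q3, mu = rbind(p@mu, p@mu[2, ]),
                     trans = smoothTransitions(matrix(1 / 3, 3, 3), 0.01),
                     initDist = rep(1 / 3, 3))
  ll3 <- netstates:::.loglikOn(dup, sim$observed)
  b2 <- bicARHMM(ll2, sim$observed, p)
  b3 <- bicARHMM(ll3, sim$observed, dup)
  expect_gt(b3, b2)
})

test_that("the model-selection sweep has the right shape", {
  sim <- quickSim(seed = 55, nTrials = 12, trialLength = 200, snr = 30)
  sel <- selectModel(sim$observed, kRange = c(2, 3), orderRange = c(1, 2),
                     heldoutFraction = 0.2, seed = 1)
  expect_equal(nrow(sel$table), 4L)
  expect_true(all(c("k", "order", "bic", "heldout_loglik_per_sample")
                  %in% names(sel$table)))
  expect_true(sel$bestK %in% c(2, 3))
  sel1 <- selectModel(sim$observed, kRange = 2, orderRange = 1,
                      heldoutFraction = 0.25, seed = 1)
  expect_equal(nrow(sel1$table), 1L)
  expect_error(selectModel(sim$observed, 2, 1, heldoutFraction = 0.01),
               "split")
})
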