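test_that("ground-truth parameters are stable, distinct and reproducible", {
  cfg <- simConfig(nStates = 3, nChannels = 6, arOrder = 3, nTrials = 5,
                   trialLength = 100, seed = 7)
  p1 <- makeGroundTruthParams(cfg)
  p2 <- makeGroundTruthParams(cfg)
  expect_identical(p1@A, p2@A)
  expect_identical(p1@Q, p2@Q)
  # eigenvalue oracle on the companion matrix: every state stable
  for (z in 1:3) {
    C <- companionMatrix(arCoefficients(p1, z))
    expect_lt(max(Mod(eigen(C, only.values = TRUE)$values)), 0.99)
  }
  # pairwise-distinct directed networks
  ip <- statePDC(p1, rate = 200)
  for (a in 1:2) for (b in (a + 1):3)
    expect_gt(pdcDissimilarity(ip[[a]], ip[[b]]), 0.1)
  # transition matrix row-stochastic with dominant diagonal
  expect_equal(rowSums(transitionMatrix(p1)), rep(1, 3))
  expect_true(all(diag(transitionMatrix(p1)) >
                    apply(transitionMatrix(p1) - diag(diag(transitionMatrix(p1))), 1, max)))
})

test_that("degenerate single-state scalar config yields |a| < 1 and trans [1]", {
  cfg <- simConfig(nStates = 1, nChannels = 1, arOrder = 1, nTrials = 2,
                   trialLength = 50, seed = 3)
  p <- makeGroundTruthParams(cfg)
  expect_lt(abs(p@A[1, 1, 1, 1]), 1)
  expect_equal(transitionMatrix(p), matrix(1, 1, 1))
})

test_that("near-noiseless single-state AR(1) decays geometrically", {
  A <- array(0.5, c(1, 1, 1, 1))
  p <- ARHMMParams(A, array(1e-20, c(1, 1, 1)), trans = matrix(1),
                   initDist = 1)
  cfg <- simConfig(nStates = 1, nChannels = 1, arOrder = 1, nTrials = 1,
                   trialLength = 60, scheduleMode = "fixed_blocks",
                   meanNoiseGain = 0, seed = 5)
  sim <- simulateDataset(p, cfg)
  x <- as.numeric(trialData(sim$observed, 1))
  expect_equal(x[2:60], 0.5 * x[1:59], tolerance = 1e-6)
})

test_that("markov schedule dwell times follow the geometric law", {
  # diag 0.9 -> geometric(0.1): mean dwell 10 samples
  cfg <- simConfig(nStates = 2, nChannels = 2, arOrder = 1, nTrials = 60,
                   trialLength = 2000, scheduleMode = "markov",
                   selfTransition = 0.9, meanNoiseGain = 0, seed = 11)
  sim <- simulateDataset(makeGroundTruthParams(cfg), cfg)
  dwell <- unlist(lapply(truthRaster(sim$truth), function(z) {
    r <- rle(z)$lengths
    r[-length(r)]                    # last run is censored
  }))
  expect_gt(length(dwell), 5000)
  expect_equal(mean(dwell), 10, tolerance = 0.05)
  # geometric shape: P(dwell > 10)/P(dwell > 5) close to 0.9^5
  expect_equal(mean(dwell > 10) / mean(dwell > 5), 0.9^5,
               tolerance = 0.06)
})

test_that("fixed-block schedule is an exact passthrough", {
  cfg <- simConfig(nStates = 3, nChannels = 2, arOrder = 1, nTrials = 2,
                   trialLength = 90, scheduleMode = "fixed_blocks",
                   seed = 2)
  sim <- simulateDataset(makeGroundTruthParams(cfg), cfg)
  expect_equal(truthRaster(sim$truth)[[1]], rep(1:3, each = 30))
})

test_that("variable-block schedules vary across trials with ordered states", {
  sim <- quickSim(seed = 21, nTrials = 20, trialLength = 400)
  rs <- truthRaster(sim$truth)
  lens1 <- vapply(rs, function(z) rle(z)$lengths[1], 1)
  expect_gt(length(unique(lens1)), 3)       # durations vary by trial
  for (z in rs) expect_equal(rle(z)$values, 1:3)
})

test_that("identical config and seed reproduce the dataset bit-exactly", {
  s1 <- quickSim(seed = 9, nTrials = 4, trialLength = 120, snr = 3)
  s2 <- quickSim(seed = 9, nTrials = 4, trialLength = 120, snr = 3)
  expect_identical(s1$observed@data, s2$observed@data)
  expect_identical(truthRaster(s1$truth), truthRaster(s2$truth))
})

test_that("observation noise hits the requested SNR per channel", {
  # white unit-variance signal; SNR calibration to within 5%
  clean <- withr::with_seed(1, TrialTensor(
    lapply(1:500, function(i) matrix(rnorm(2 * 1000), 2, 1000)), rate = 200))
  noisy <- corruptObservations(clean, snr = 1, seed = 2)
  noise <- do.call(cbind, Map(`-`, noisy@data, clean@data))
  sig <- do.call(cbind, clean@data)
  ratio <- apply(sig, 1, var) / apply(noise, 1, var)
  expect_equal(ratio, c(1, 1), tolerance = 0.05, ignore_attr = TRUE)

  noisy30 <- corruptObservations(clean[1:200], snr = 30, seed = 3)
  noise30 <- do.call(cbind, Map(`-`, noisy30@data, clean[1:200]@data))
  sig30 <- do.call(cbind, clean[1:200]@data)
  ratio30 <- apply(sig30, 1, var) / apply(noise30, 1, var)
  expect_equal(ratio30, c(30, 30), tolerance = 0.1, ignore_attr = TRUE)

  expect_identical(corruptObservations(clean, snr = Inf), clean)
  expect_error(corruptObservations(clean, snr = -1), "positive")
})

test_that("mean-dependent process noise inflates variance where the mean is large", {
  base <- simConfig(nStates = 1, nChannels = 3, arOrder = 1, nTrials = 40,
                    trialLength = 300, scheduleMode = "fixed_blocks",
                    meanNoiseGain = 0, seed = 13)
  p <- makeGroundTruthParams(base)
  p@mu[1, ] <- 3                       # large stationary mean
  modded <- simConfig(nStates = 1, nChannels = 3, arOrder = 1,
                      nTrials = 40, trialLength = 300,
                      scheduleMode = "fixed_blocks",
                      meanNoiseGain = 0.5, seed = 13)
  v0 <- var(as.numeric(trialData(simulateDataset(p, base)$observed, 1)))
  vs <- var(as.numeric(trialData(simulateDataset(p, modded)$observed, 1)))
  expect_gt(vs, 1.5 * v0)
})
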