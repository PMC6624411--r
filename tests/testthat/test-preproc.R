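mkTrials <- function(X, rate, events = NULL)
  TrialTensor(list(X), rate = rate, events = events)

test_that("common-average referencing removes the common mode exactly", {
  X <- matrix(c(1, 2, 3), 3, 4)
  out <- commonAverage(mkTrials(X, 10))
  expect_equal(trialData(out, 1), matrix(c(-1, 0, 1), 3, 4))
  # zero-mean input is untouched
  X2 <- matrix(c(1, -1), 2, 5)
  expect_equal(trialData(commonAverage(mkTrials(X2, 10)), 1), X2)
  # a common offset is rejected entirely
  X3 <- matrix(rnorm(20), 4, 5)
  ref1 <- commonAverage(mkTrials(X3, 10))
  ref2 <- commonAverage(mkTrials(X3 + 7, 10))
  expect_equal(trialData(ref1, 1), trialData(ref2, 1))
  expect_error(commonAverage(mkTrials(X3, 10), includeMask = 1),
               "at least 2")
})

test_that("band-power filter passes in-band envelope power and rejects stopband", {
  rate <- 1000; T <- 2000; A <- 2
  tt <- (0:(T - 1)) / rate
  band <- bandSpec(60, 120, 1)
  mid <- sin(2 * pi * 90 * tt) * A
  out <- bandpowerHilbert(mkTrials(rbind(mid), rate), band)
  core <- trialData(out, 1)[1, 200:1800]
  expect_equal(mean(core), A^2, tolerance = 0.02)
  expect_lt(max(abs(core - A^2)) / A^2, 0.02)

  stop <- sin(2 * pi * 360 * tt) * A       # 3x the upper edge
  outS <- bandpowerHilbert(mkTrials(rbind(stop), rate), band)
  expect_lt(max(trialData(outS, 1)[1, ]), 0.01 * A^2)

  zero <- bandpowerHilbert(mkTrials(matrix(0, 1, 500), rate), band)
  expect_equal(trialData(zero, 1), matrix(0, 1, 500))
  # power is nonnegative for arbitrary signals
  rnd <- withr::with_seed(4, matrix(rnorm(2 * 800), 2, 800))
  expect_true(all(trialData(bandpowerHilbert(mkTrials(rnd, rate), band), 1) >= 0))
  expect_error(bandpowerHilbert(mkTrials(rnd, rate), bandSpec(60, 600)),
               "Nyquist")
})

test_that("baseline normalization divides by the prestimulus mean", {
  X <- matrix(2, 1, 100)
  X[1, 51:100] <- 6
  ev <- data.frame(stimulus_onset = 0.5)
  out <- baselineNormalize(mkTrials(X, 100, ev), window = c(-0.3, -0.1))
  expect_equal(trialData(out, 1)[1, 1], 1)    # baseline mean 2 -> 1
  expect_equal(trialData(out, 1)[1, 60], 3)   # 6 / 2
  # constant trial normalizes to all ones
  out2 <- baselineNormalize(mkTrials(matrix(5, 2, 100), 100, ev),
                            window = c(-0.3, -0.1))
  expect_equal(trialData(out2, 1), matrix(1, 2, 100))
  expect_error(baselineNormalize(mkTrials(matrix(0, 1, 100), 100, ev),
                                 window = c(-0.3, -0.1)), "baseline")
})

test_that("resampling decimates with DC preservation and keeps event times", {
  ev <- data.frame(stimulus_onset = 0.5)
  const <- mkTrials(matrix(3, 2, 1000), 1000, ev)
  out <- resampleTrials(const, 200)
  expect_equal(nSamples(out), 200L)
  expect_equal(samplingRate(out), 200)
  mid <- trialData(out, 1)[, 20:180]
  expect_equal(mean(mid), 3, tolerance = 1e-6)
  expect_equal(trialEvents(out)$stimulus_onset, 0.5)
  expect_identical(resampleTrials(const, 1000), const)
  expect_error(resampleTrials(const, 2000), "upsampling")
})

test_that("reaction-time filter uses strict bounds and preserves order", {
  tt <- TrialTensor(lapply(1:4, function(i) matrix(i, 1, 10)), rate = 2,
                    events = data.frame(stimulus_onset = rep(0, 4),
                                        articulation_onset =
                                          c(0.5, 1.0, 3.0, 0.6)))
  kept <- filterTrialsByRT(tt)        # defaults 0.6 / 2.8 s
  expect_equal(nTrials(kept), 1L)     # rt = 0.6 is excluded (strict)
  expect_equal(trialData(kept, 1)[1, 1], 2)
  # boundary value exactly at the lower cut leaves nothing
  tt2 <- TrialTensor(list(matrix(0, 1, 10)), rate = 2,
                     events = data.frame(stimulus_onset = 0,
                                         articulation_onset = 0.6))
  expect_error(filterTrialsByRT(tt2), "no trials")
})

test_that("region meta-electrodes extract the leading principal component", {
  # two perfectly correlated channels: meta-electrode correlates 1 with each
  base <- withr::with_seed(5, rnorm(500))
  X <- rbind(base, 2 * base, rnorm(500))
  tt <- TrialTensor(list(X), rate = 100)
  out <- regionPrincipalComponent(tt, list(r1 = 1:2, r2 = 3))
  expect_equal(nChannels(out), 2L)
  expect_equal(channelLabels(out), c("r1", "r2"))
  expect_equal(abs(cor(trialData(out, 1)[1, ], base)), 1, tolerance = 1e-10)
  # singleton region passes through unchanged
  expect_equal(trialData(out, 1)[2, ], unname(X[3, ]))
  # two independent equal-variance channels: leading PC ~ 50% variance
  Y <- withr::with_seed(6, matrix(rnorm(2 * 20000), 2, 20000))
  M <- t(Y)
  ev <- eigen(cov(scale(M)))$values
  expect_equal(ev[1] / sum(ev), 0.5, tolerance = 0.05)
  out2 <- regionPrincipalComponent(TrialTensor(list(Y), rate = 100),
                                   list(a = 1:2))
  expect_equal(var(trialData(out2, 1)[1, ]) / 2, 0.5, tolerance = 0.05)
  expect_error(regionPrincipalComponent(tt, list(a = 1:2, b = 2:3)),
               "disjoint")
})

test_that("the pipeline runner applies stages in the canonical order", {
  rate <- 1000
  tt <- (0:(3 * rate - 1)) / rate
  trials <- lapply(1:6, function(i) {
    sig <- 1 + 0.5 * sin(2 * pi * 0.8 * tt + i)
    rbind(sig * sin(2 * pi * 80 * tt), sig * sin(2 * pi * 100 * tt)) +
      withr::with_seed(i, matrix(rnorm(2 * length(tt), 0, 0.01), 2))
  })
  raw <- TrialTensor(trials, rate = rate,
                     events = data.frame(stimulus_onset = rep(0.8, 6),
                                         articulation_onset =
                                           0.8 + c(0.7, 0.9, 1.1, 0.5, 0.65, 0.8)))
  out <- preprocessTrials(raw, band = bandSpec(60, 120),
                          baselineWindow = c(-0.5, -0.2),
                          targetRate = 200, rtRange = c(0.6, 2.8))
  expect_equal(samplingRate(out), 200)
  expect_equal(nTrials(out), 5L)     # the RT = 0.5 s trial is dropped
  expect_true(all(vapply(out@data, function(m) all(is.finite(m)), TRUE)))
})
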