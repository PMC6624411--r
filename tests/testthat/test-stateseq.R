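mkRaster <- function(states, rate = 10, events = NULL, probs = NULL,
                     K = max(unlist(states))) {
  n <- length(states)
  ev <- data.frame(stimulus_onset = rep(NA_real_, n),
                   articulation_onset = NA_real_,
                   articulation_offset = NA_real_,
                   reaction_time = NA_real_)
  if (!is.null(events)) for (col in names(events)) ev[[col]] <- events[[col]]
  if (is.null(probs)) probs <- lapply(states, function(z) rep(1, length(z)))
  new("StateRaster", states = lapply(states, as.integer), probs = probs,
      rate = rate, events = ev, nStates = as.integer(K))
}

test_that("majority filtering smooths blips and fixes long runs", {
  z <- c(rep(1L, 10), 2L, rep(1L, 10))
  r <- mkRaster(list(z), rate = 10)
  filt <- majorityFilter(r, window = 0.5)       # 5-sample window
  expect_equal(filt@states[[1]], rep(1L, 21))
  # constant sequences are fixed points
  r2 <- mkRaster(list(rep(2L, 30)), K = 3)
  expect_equal(majorityFilter(r2, 0.4)@states[[1]], rep(2L, 30))
  # idempotent when all runs exceed the window
  z3 <- rep(c(1L, 2L), each = 15)
  r3 <- mkRaster(list(z3))
  once <- majorityFilter(r3, 0.5)
  twice <- majorityFilter(once, 0.5)
  expect_equal(once@states, twice@states)
  # ties resolved by summed responsibility, then lower index
  zt <- c(1L, 1L, 2L, 2L)
  rHigh2 <- mkRaster(list(zt), probs = list(c(0.5, 0.5, 0.9, 0.9)))
  filtH <- majorityFilter(rHigh2, 0.4)          # 4-sample windows
  expect_equal(filtH@states[[1]][2], 2L)        # state 2 carries more mass
  rEq <- mkRaster(list(zt), probs = list(rep(0.8, 4)))
  expect_equal(majorityFilter(rEq, 0.4)@states[[1]][2], 1L)
})

test_that("state durations conserve the interval exactly", {
  rate <- 200
  z <- c(rep(1L, 250), rep(2L, 250), rep(3L, 240))   # 3.7 s of samples
  r <- mkRaster(list(z, rep(2L, 740)), rate = rate,
                events = list(stimulus_onset = c(0.1, 0.1)), K = 3)
  dur <- stateDurations(r, interval = c(0, 3.2))
  expect_equal(rowSums(dur), c(3.2, 3.2))
  expect_equal(dur[2, ], c(0, 3.2, 0), ignore_attr = TRUE)
  # equal thirds of the interval
  z3 <- c(rep(1L, 20), rep(1:3, each = 640 / 3 + 1)[1:640], rep(3L, 80))
  r3 <- mkRaster(list(z3), rate = rate,
                 events = list(stimulus_onset = 0.1), K = 3)
  d3 <- stateDurations(r3, interval = c(0, 3.2))
  expect_equal(sum(d3), 3.2)
  expect_equal(as.numeric(d3), rep(3.2 / 3, 3), tolerance = 0.01)
  expect_error(stateDurations(r3, interval = c(0, 10)), "beyond trial")
})

test_that("language-state termination lands at the end of the target block", {
  rate <- 100
  # one contiguous state-2 block from 0.5 s to 1.5 s
  z <- c(rep(1L, 50), rep(2L, 100), rep(3L, 100))
  r <- mkRaster(list(z), rate = rate,
                events = list(stimulus_onset = 0.2,
                              articulation_onset = 1.5,
                              articulation_offset = 2.2,
                              reaction_time = 1.3), K = 3)
  off <- languageOffset(r, targetState = 2, window = 0.1)
  expect_equal(off, 1.5, tolerance = 0.05 + 1 / rate)  # within half a window
  # a trial never visiting the target state yields NA
  rNo <- mkRaster(list(rep(1L, 250)), rate = rate,
                  events = list(stimulus_onset = 0.2,
                                articulation_onset = 1.5,
                                articulation_offset = 2.2,
                                reaction_time = 1.3), K = 3)
  expect_true(is.na(languageOffset(rNo, targetState = 2)))
  # brute-force scan oracle over every window center
  h <- floor(round(0.1 * rate) / 2)
  centers <- which((seq_along(z) - 1) / rate >= 0.2 &
                     (seq_along(z) - 1) / rate <= 2.2)
  modal <- vapply(centers, function(t) {
    w <- z[max(1, t - h):min(length(z), t + h)]
    as.integer(names(which.max(table(w))))
  }, 1L)
  want <- (centers[max(which(modal == 2L))] - 1) / rate
  expect_equal(off, want)
})

test_that("the Fisher-transform p value matches its closed form", {
  x0 <- 1:10
  expect_equal(corrFisherP(x0, (x0 - 5.5)^2)$p, 1)        # r = 0 exactly
  # n = 10, r = 0.5 -> p = erfc(atanh(0.5) sqrt(7)/sqrt(2)) ~ 0.146
  pr <- exactCorPair(0.5, 10)
  got <- corrFisherP(pr$x, pr$y)
  expect_equal(got$r, 0.5, tolerance = 1e-12)
  expect_equal(got$p, pracma::erfc(atanh(0.5) * sqrt(7) / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(got$p, 0.146, tolerance = 0.005)
  # agreement with the printed form 1 + erf(-x) across a grid of (r, n)
  for (r in c(0.1, 0.3, 0.6, 0.9)) for (n in c(8, 20, 50)) {
    pr <- exactCorPair(r, n, seed = round(100 * r) + n)
    got <- corrFisherP(pr$x, pr$y)
    printed <- 1 + pracma::erf(-atanh(abs(got$r)) * sqrt(n - 3) / sqrt(2))
    expect_lt(abs(got$p - printed), 1e-14)
  }
  # p is monotone decreasing in |r| at fixed n
  ps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(r)
    corrFisherP(exactCorPair(r, 12)$x, exactCorPair(r, 12)$y)$p, 1)
  expect_true(all(diff(ps) < 0))
  # |r| = 1 is flagged and clipped to p = 0
  got1 <- corrFisherP(1:8, 2 * (1:8) + 3)
  expect_true(got1$degenerate)
  expect_equal(got1$p, 0)
  expect_error(corrFisherP(1:3, 1:3), "at least 4")
  expect_error(corrFisherP(1:8, rep(1, 8)), "variance")
})

test_that("behavior report links constructed durations to reaction times", {
  rate <- 100
  n <- 24
  rts <- withr::with_seed(7, runif(n, 0.7, 1.6))
  # language state (2) lasts exactly RT - 0.25 s, starting 0.25 s after
  # stimulus; trial spans 3.5 s with stimulus at 0.1 s
  states <- lapply(rts, function(rt) {
    stim <- round(0.1 * rate)
    lang <- round((rt - 0.25) * rate)
    c(rep(1L, stim + round(0.25 * rate)), rep(2L, lang),
      rep(3L, 350 - stim - round(0.25 * rate) - lang))
  })
  ev <- list(stimulus_onset = rep(0.1, n),
             articulation_onset = 0.1 + rts,
             articulation_offset = pmin(3.5, 0.6 + rts),
             reaction_time = rts)
  r <- mkRaster(states, rate = rate, events = ev, K = 3)
  tab <- durationBehaviorReport(r, languageState = 2,
                                interval = c(0, 3.2))
  d2 <- tab[tab$state == 2 & tab$statistic == "duration_vs_rt", ]
  expect_gt(d2$r, 0.99)
  off <- tab[tab$statistic == "offset_vs_rt", ]
  expect_gt(off$r, 0.95)
  # state 1 lasts a fixed 0.25 s (zero variance -> no row); states 2 and
  # 3 each get a duration row, plus the offset row
  expect_equal(sum(tab$statistic == "duration_vs_rt"), 2L)
  expect_equal(nrow(tab), 3L)
  # shuffled RTs should decorrelate
  evS <- ev
  evS$reaction_time <- withr::with_seed(8, sample(rts))
  evS$articulation_onset <- 0.1 + evS$reaction_time
  rs <- mkRaster(states, rate = rate, events = evS, K = 3)
  tabS <- durationBehaviorReport(rs, languageState = 2,
                                 interval = c(0, 3.2))
  expect_lt(abs(tabS[tabS$state == 2 &
                       tabS$statistic == "duration_vs_rt", "r"]), 0.5)
})
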