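# Plain-text container IO and the pipeline runner. The trial container is
# a directory of per-trial CSV matrices (samples x channels, header row of
# channel labels) plus events.csv and meta.json; numeric round-trips are
# exact to better than 1e-12 relative. Sample indices are 1-based in all
# human-facing CSV exports.

#' Write a TrialTensor to a CSV-directory container
#'
#' Layout: `trial_0001.csv`, ... (samples x channels with a header row),
#' `events.csv` (trial, stimulus_onset, articulation_onset,
#' articulation_offset, reaction_time) and `meta.json` (rate, channel
#' labels, trial count).
#'
#' @param trials a [TrialTensor-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeTrials <- function(trials, path) {
  stopifnot(is(trials, "TrialTensor"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nTrials(trials))) {
    df <- as.data.frame(t(trialData(trials, i)))
    names(df) <- channelLabels(trials)
    write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
              file.path(path, sprintf("trial_%04d.csv", i)),
              row.names = FALSE, quote = FALSE)
  }
  ev <- cbind(trial = seq_len(nTrials(trials)), trialEvents(trials))
  write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  meta <- list(rate = samplingRate(trials),
               channel_labels = channelLabels(trials),
               n_trials = nTrials(trials))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Read a TrialTensor from a CSV-directory container
#'
#' Accepts the layout written by [writeTrials()]; per-trial CSVs may have
#' a header row of channel labels or none. Missing `meta.json` rate or a
#' malformed events table is a format error naming the missing field.
#'
#' @param path container directory.
#' @return a [TrialTensor-class].
#' @export
readTrials <- function(path) {
  metaFile <- file.path(path, "meta.json")
  if (!file.exists(metaFile)) stop("container missing meta.json")
  meta <- jsonlite::fromJSON(metaFile)
  if (is.null(meta$rate)) stop("meta.json missing required field 'rate'")
  files <- sort(list.files(path, pattern = "^trial_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("container has no trial_*.csv files")
  labels <- meta$channel_labels
  data <- lapply(files, function(f) {
    first <- strsplit(readLines(f, n = 1L), ",")[[1L]]
    hasHeader <- any(is.na(suppressWarnings(as.numeric(first))))
    m <- as.matrix(read.csv(f, header = hasHeader))
    t(unname(m))
  })
  ev <- NULL
  evFile <- file.path(path, "events.csv")
  if (file.exists(evFile)) {
    ev <- read.csv(evFile)
    ev <- ev[order(ev$trial), setdiff(names(ev), "trial"), drop = FALSE]
  }
  TrialTensor(data, rate = meta$rate, channelLabels = labels, events = ev)
}

#' Write / read ARHMM parameters as JSON
#'
#' Stores the flat parameter values together with their dimensions; the
#' round-trip is exact to near machine precision (~1e-15 relative).
#'
#' @param params an [ARHMMParams-class].
#' @param path JSON file path.
#' @return `writeParams`: `path` invisibly; `readParams`: the
#'   [ARHMMParams-class].
#' @export
writeParams <- function(params, path) {
  stopifnot(is(params, "ARHMMParams"))
  obj <- list(dims = list(K = nStates(params), order = arOrder(params),
                          D = nChannels(params)),
              A = as.numeric(params@A), Q = as.numeric(params@Q),
              mu = as.numeric(params@mu),
              trans = as.numeric(params@trans),
              initDist = params@initDist)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  obj <- jsonlite::fromJSON(path)
  K <- obj$dims$K; P <- obj$dims$order; D <- obj$dims$D
  new("ARHMMParams",
      A = array(obj$A, c(K, P, D, D)),
      Q = array(obj$Q, c(K, D, D)),
      mu = matrix(obj$mu, K, D),
      trans = matrix(obj$trans, K, K),
      initDist = obj$initDist)
}

#' Export a ground-truth raster as CSV
#'
#' Columns `trial`, `sample` (1-based), `state`.
#'
#' @param truth a [GroundTruth-class] or [StateRaster-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(truth, path) {
  states <- if (is(truth, "GroundTruth")) truth@stateRaster else
    truth@states
  df <- do.call(rbind, lapply(seq_along(states), function(i)
    data.frame(trial = i, sample = seq_along(states[[i]]),
               state = states[[i]])))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%d", h)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order: simulate (or read)
#' -> preprocess -> init -> fit / select -> connectivity + report +
#' diagnose, writing every artifact under `config$out`. Each stage is
#' stamped with a hash of its configuration and the seed; a rerun with an
#' unchanged configuration skips completed stages. One master seed fans
#' out to per-stage seeds via [deriveSeed()].
#'
#' @param config named list (or path to a JSON file) with entries `seed`,
#'   `out`, and per-stage sublists `simulate` (or `input` = container
#'   path), optional `preprocess`, `fit` (states, order, ...), optional
#'   `select` (states, orders, heldout), `connectivity`, `report`,
#'   `diagnose`. See the pipeline vignette for the full schema.
#' @param force rerun all stages even when cached (default FALSE).
#' @return invisibly, a list with the in-memory results (`trials`,
#'   `truth`, `fit`, `selection`, `pdc`, `report`, `whiteness`) and the
#'   artifact directory.
#' @export
runPipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$out
  if (is.null(out)) stop("config$out (artifact directory) is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(stage) file.path(out, paste0(".", stage, ".stamp"))
  cached <- function(stage, cfg) {
    !force && file.exists(stamp(stage)) &&
      identical(readLines(stamp(stage))[1L],
                .configHash(list(cfg, seed)))
  }
  mark <- function(stage, cfg)
    writeLines(.configHash(list(cfg, seed)), stamp(stage))
  res <- list(out = out)

  # --- acquire trials -------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    cfg <- simConfig(
      nStates = sc$states %||% 3L, nChannels = sc$channels %||% 6L,
      arOrder = sc$order %||% 2L, nTrials = sc$trials %||% 100L,
      trialLength = sc$length %||% 400L, rate = sc$rate %||% 200,
      scheduleMode = sc$schedule %||% "variable_blocks",
      snr = sc$snr %||% Inf, meanNoiseGain = sc$mean_noise_gain %||% 0.5,
      seed = deriveSeed(seed, "simulate"))
    params <- makeGroundTruthParams(cfg)
    sim <- simulateDataset(params, cfg)
    trials <- sim$observed
    truth <- sim$truth
    if (!cached("simulate", sc)) {
      writeTrials(trials, file.path(out, "trials"))
      writeRaster(truth, file.path(out, "truth_raster.csv"))
      writeParams(params, file.path(out, "truth_params.json"))
      mark("simulate", sc)
    }
  } else if (!is.null(config$input)) {
    trials <- readTrials(config$input)
  } else stop("config needs either 'simulate' or 'input'")
  res$trials <- trials
  res$truth <- truth

  # --- preprocess -----------------------------------------------------
  if (!is.null(config$preprocess)) {
    pp <- config$preprocess
    band <- bandSpec(pp$band[1L] %||% 60, pp$band[2L] %||% 120,
                     pp$flank %||% 1)
    trials <- preprocessTrials(
      trials, band = band,
      baselineWindow = pp$baseline %||% c(-0.7, -0.2),
      targetRate = pp$rate %||% 200,
      rtRange = pp$rt %||% c(0.6, 2.8))
    res$trials <- trials
  }

  # --- model selection (optional) ------------------------------------
  fitCfg <- config$fit %||% list()
  K <- fitCfg$states %||% 3L
  P <- fitCfg$order %||% 2L
  if (!is.null(config$select)) {
    sel <- selectModel(trials, kRange = config$select$states %||% 2:4,
                       orderRange = config$select$orders %||% 1:3,
                       heldoutFraction = config$select$heldout %||% 0.2,
                       seed = deriveSeed(seed, "select"))
    res$selection <- sel
    write.csv(sel$table, file.path(out, "model_selection.csv"),
              row.names = FALSE)
    K <- sel$bestK; P <- sel$bestOrder
  }

  # --- init + fit -----------------------------------------------------
  init <- amvarInit(trials, k = K, order = P,
                    winLen = fitCfg$win %||% 0.1,
                    winStep = fitCfg$step %||% 0.05,
                    u = fitCfg$stickiness %||% 0.5,
                    seed = deriveSeed(seed, "init"))
  fit <- fitARHMM(trials, init,
                  maxIter = fitCfg$max_iter %||% 200L,
                  tol = fitCfg$tol %||% 1e-6,
                  nRestarts = fitCfg$restarts %||% 3L,
                  stickiness = fitCfg$stickiness %||% 0.5,
                  seed = deriveSeed(seed, "fit"))
  res$fit <- fit
  writeParams(fittedParams(fit), file.path(out, "fitted_params.json"))
  gdf <- do.call(rbind, lapply(seq_len(nTrials(trials)), function(i) {
    g <- responsibilities(posterior(fit), i)
    data.frame(trial = i, sample = rep(seq_len(nrow(g)), ncol(g)),
               state = rep(seq_len(ncol(g)), each = nrow(g)),
               probability = as.numeric(g))
  }))
  write.csv(gdf, file.path(out, "gamma.csv"), row.names = FALSE)
  vit <- new("StateRaster",
             states = lapply(seq_len(nTrials(trials)), function(i)
               viterbiPath(fittedParams(fit), trials, i)),
             probs = lapply(nSamples(trials), function(T) rep(1, T)),
             rate = samplingRate(trials), events = trialEvents(trials),
             nStates = as.integer(K))
  writeRaster(vit, file.path(out, "viterbi_raster.csv"))

  # --- connectivity ---------------------------------------------------
  cc <- config$connectivity %||% list()
  grid <- seq(0, samplingRate(trials) / 2,
              length.out = cc$grid %||% 256L)
  ip <- statePDC(fittedParams(fit), freqs = grid,
                 rate = samplingRate(trials))
  res$pdc <- ip
  for (z in seq_along(ip)) {
    write.csv(ip[[z]]@matrix,
              file.path(out, sprintf("pdc_state%d.csv", z)),
              row.names = FALSE)
    write.csv(exportGraph(ip[[z]], channelLabels(trials),
                          threshold = cc$threshold %||% 0.1),
              file.path(out, sprintf("edges_state%d.csv", z)),
              row.names = FALSE)
  }
  dis <- outer(seq_along(ip), seq_along(ip),
               Vectorize(function(a, b)
                 pdcDissimilarity(ip[[a]], ip[[b]])))
  write.csv(dis, file.path(out, "state_dissimilarity.csv"),
            row.names = FALSE)

  # --- behavioral report ---------------------------------------------
  rp <- config$report %||% list()
  if (sum(is.finite(trialEvents(trials)$reaction_time)) >= 4L) {
    ras <- stateRaster(fit, trials)
    stim <- trialEvents(trials)$stimulus_onset
    maxEnd <- min(nSamples(trials) / samplingRate(trials) -
                    ifelse(is.finite(stim), stim, 0))
    behav <- tryCatch(
      durationBehaviorReport(ras,
                             languageState = rp$language_state %||% 2L,
                             interval = rp$interval %||%
                               c(0, min(3.2, maxEnd))),
      error = function(e) NULL)
    if (!is.null(behav)) {
      res$report <- behav
      write.csv(behav, file.path(out, "behavior_correlations.csv"),
                row.names = FALSE)
    }
  }

  # --- diagnostics ----------------------------------------------------
  resid <- modelResiduals(fit, trials)
  wh <- whitenessTest(resid, maxLag = P)
  res$whiteness <- wh
  writeLines(jsonlite::toJSON(list(
    lags = wh@lags, max_abs = wh@maxAbs, threshold = wh@threshold,
    pass_fraction = wh@passFrac, pass = wh@pass, n = wh@n),
    auto_unbox = TRUE, digits = NA),
    file.path(out, "whiteness.json"))
  for (l in wh@lags)
    write.csv(matrix(wh@corr[l, , ], dim(wh@corr)[2L]),
              file.path(out, sprintf("whiteness_lag%d.csv", l)),
              row.names = FALSE)

  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
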