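#' Construct a TrialTensor
#'
#' Builds the package's universal data carrier from per-trial
#' channels-by-samples matrices (or a `trials x channels x samples` array),
#' a sampling rate, optional channel labels and optional behavioral event
#' markers.
#'
#' @param data list of numeric `channels x samples` matrices, or a 3-d
#'   array `trials x channels x samples`.
#' @param rate sampling rate in Hz.
#' @param channelLabels character channel names; defaults to
#'   `"ch1".."chD"`.
#' @param events data.frame with one row per trial and any of the columns
#'   `stimulus_onset`, `articulation_onset`, `articulation_offset`,
#'   `reaction_time` (seconds from trial start). Missing columns are
#'   filled with `NA`; `reaction_time` is derived from onset markers when
#'   both are present.
#' @return a [TrialTensor-class] object.
#' @examples
#' tt <- TrialTensor(list(matrix(rnorm(20), 2, 10)), rate = 10)
#' nTrials(tt); nChannels(tt)
#' @export
TrialTensor <- function(data, rate, channelLabels = NULL, events = NULL) {
  if (is.array(data) && length(dim(data)) == 3L)
    data <- lapply(seq_len(dim(data)[1L]), function(i)
      matrix(data[i, , ], dim(data)[2L], dim(data)[3L]))
  if (!is.list(data)) stop("data must be a list of matrices or a 3-d array")
  data <- lapply(data, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  D <- nrow(data[[1L]])
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(D))
  n <- length(data)
  ev <- data.frame(matrix(NA_real_, n, length(.EVENT_COLS)))
  names(ev) <- .EVENT_COLS
  if (!is.null(events)) {
    if (nrow(events) != n) stop("events must have one row per trial")
    for (col in intersect(names(events), .EVENT_COLS))
      ev[[col]] <- as.numeric(events[[col]])
  }
  need <- is.na(ev$reaction_time) & !is.na(ev$stimulus_onset) &
    !is.na(ev$articulation_onset)
  ev$reaction_time[need] <- ev$articulation_onset[need] -
    ev$stimulus_onset[need]
  new("TrialTensor", data = data, rate = as.numeric(rate),
      channelLabels = as.character(channelLabels), events = ev)
}

#' @describeIn TrialTensor number of trials
#' @param x a `TrialTensor`
#' @export
setMethod("nTrials", "TrialTensor", function(x) length(x@data))

#' @describeIn TrialTensor number of channels
#' @export
setMethod("nChannels", "TrialTensor", function(x) nrow(x@data[[1L]]))

#' @describeIn TrialTensor per-trial sample counts
#' @export
setMethod("nSamples", "TrialTensor",
          function(x) vapply(x@data, ncol, 1L))

#' @describeIn TrialTensor sampling rate in Hz
#' @export
setMethod("samplingRate", "TrialTensor", function(x) x@rate)

#' @describeIn TrialTensor channel labels
#' @export
setMethod("channelLabels", "TrialTensor", function(x) x@channelLabels)

#' @describeIn TrialTensor behavioral event table
#' @export
setMethod("trialEvents", "TrialTensor", function(x) x@events)

#' @describeIn TrialTensor the `channels x samples` matrix of trial `i`
#' @param i trial index
#' @export
setMethod("trialData", "TrialTensor", function(x, i) x@data[[i]])

setMethod("show", "TrialTensor", function(object) {
  Ts <- nSamples(object)
  cat(sprintf("TrialTensor: %d trial(s), %d channel(s), %s sample(s) @ %g Hz\n",
              nTrials(object), nChannels(object),
              if (length(unique(Ts)) == 1L) as.character(Ts[1L])
              else sprintf("%d-%d", min(Ts), max(Ts)),
              samplingRate(object)))
  cat("  channels:", paste(head(channelLabels(object), 8L), collapse = ", "),
      if (nChannels(object) > 8L) "..." else "", "\n")
  nev <- sum(!is.na(object@events$stimulus_onset))
  cat(sprintf("  events: stimulus onset present in %d/%d trials\n",
              nev, nTrials(object)))
})

#' Subset trials of a TrialTensor
#'
#' @param x a [TrialTensor-class]
#' @param i trial indices (integer or logical)
#' @param j,...,drop ignored
#' @return a `TrialTensor` containing the selected trials in order.
#' @export
setMethod("[", "TrialTensor", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nTrials(x))[i]
  new("TrialTensor", data = x@data[idx], rate = x@rate,
      channelLabels = x@channelLabels,
      events = x@events[idx, , drop = FALSE])
})
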