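#' @rdname TrialTensor
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname TrialTensor
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname TrialTensor
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname TrialTensor
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TrialTensor
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname TrialTensor
#' @export
setGeneric("trialEvents", function(x) standardGeneric("trialEvents"))

#' @rdname TrialTensor
#' @export
setGeneric("trialData", function(x, i) standardGeneric("trialData"))

#' @rdname ARHMMParams
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname ARHMMParams
#' @export
setGeneric("arOrder", function(x) standardGeneric("arOrder"))

#' @rdname ARHMMParams
#' @export
setGeneric("arCoefficients", function(x, state) standardGeneric("arCoefficients"))

#' @rdname ARHMMParams
#' @export
setGeneric("noiseCovariance", function(x, state) standardGeneric("noiseCovariance"))

#' @rdname ARHMMParams
#' @export
setGeneric("stateBias", function(x, state) standardGeneric("stateBias"))

#' @rdname ARHMMParams
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname ARHMMParams
#' @export
setGeneric("initialDistribution", function(x) standardGeneric("initialDistribution"))

#' @rdname StatePosterior
#' @export
setGeneric("responsibilities", function(x, i) standardGeneric("responsibilities"))

#' @rdname StatePosterior
#' @export
setGeneric("pairwiseMarginals", function(x, i) standardGeneric("pairwiseMarginals"))

#' @rdname StatePosterior
#' @export
setGeneric("totalLogLik", function(x) standardGeneric("totalLogLik"))

#' @rdname ARHMMFit
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

#' @rdname ARHMMFit
#' @export
setGeneric("posterior", function(x) standardGeneric("posterior"))

#' @rdname ARHMMFit
#' @export
setGeneric("loglikTrace", function(x) standardGeneric("loglikTrace"))
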