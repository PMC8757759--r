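#' @rdname GridRecording-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("recordingMode", function(x) standardGeneric("recordingMode"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("speedLabel", function(x) standardGeneric("speedLabel"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("torqueTrace", function(x) standardGeneric("torqueTrace"))

#' @rdname GridRecording-accessors
#' @export
setGeneric("torqueRate", function(x) standardGeneric("torqueRate"))

#' @rdname ActivationMap-accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname ActivationMap-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname ActivationMap-accessors
#' @export
setGeneric("mapWindow", function(x) standardGeneric("mapWindow"))

#' @rdname ActivationMap-accessors
#' @export
setGeneric("nValidChannels", function(x) standardGeneric("nValidChannels"))

#' @rdname CoGTrajectory-accessors
#' @export
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))

#' @rdname CoGTrajectory-accessors
#' @export
setGeneric("trajX", function(x) standardGeneric("trajX"))

#' @rdname CoGTrajectory-accessors
#' @export
setGeneric("trajY", function(x) standardGeneric("trajY"))

#' @rdname CoGTrajectory-accessors
#' @export
setGeneric("trajSummary", function(x, ...) standardGeneric("trajSummary"))
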