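#' @import methods
NULL

#' @rdname PoseSequence-accessors
#' @export
setGeneric("videoId", function(x) standardGeneric("videoId"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("posePosition", function(x) standardGeneric("posePosition"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("coordX", function(x) standardGeneric("coordX"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("coordY", function(x) standardGeneric("coordY"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("likelihoods", function(x) standardGeneric("likelihoods"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname PoseSequence-accessors
#' @export
setGeneric("landmarkTrack", function(x, part) standardGeneric("landmarkTrack"))

#' @rdname report-accessors
#' @export
setGeneric("mae", function(x) standardGeneric("mae"))

#' @rdname report-accessors
#' @export
setGeneric("maeSD", function(x) standardGeneric("maeSD"))

#' @rdname report-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname report-accessors
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname report-accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))
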