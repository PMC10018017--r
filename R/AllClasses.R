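#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' PoseSequence: keypoint time series for one video
#'
#' An S4 container (extending
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class])
#' holding the per-frame 2D coordinates of the 12 stick-figure landmarks of one
#' video. Rows are the landmarks (with `side` and `segment` in `rowData`),
#' columns are frames, and four assays carry the data: `x` and `y` (pixel
#' coordinates, image convention: origin top-left, y grows downward),
#' `likelihood` (tracker confidence in \[0, 1\]) and `missing` (logical mask of
#' points treated as absent). Video-level metadata (video/subject identifiers,
#' rest position, frame rate, frame size) live in `metadata()` and are exposed
#' through accessors.
#'
#' @section Validity:
#' A valid object has at least one frame, exactly the 12 canonical landmarks of
#' [bodyPartNames()], likelihoods within \[0, 1\] wherever non-`NA`, and finite
#' coordinates at every point not flagged missing.
#'
#' @seealso [PoseSequence()] for construction, [readPoseTable()] for import.
#' @aliases PoseSequence-class
#' @exportClass PoseSequence
setClass("PoseSequence", contains = "SummarizedExperiment")

setValidity("PoseSequence", function(object) {
  msgs <- character()
  needed <- c("x", "y", "likelihood", "missing")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(needed %in% have))
    return(sprintf("assays must include %s", paste(needed, collapse = ", ")))
  if (ncol(object) < 1L)
    msgs <- c(msgs, "a PoseSequence needs at least one frame")
  if (!identical(sort(rownames(object)), sort(bodyPartNames())))
    msgs <- c(msgs, "rows must be exactly the 12 canonical body parts")
  p <- SummarizedExperiment::assay(object, "likelihood")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msgs <- c(msgs, "likelihoods must lie in [0, 1]")
  miss <- SummarizedExperiment::assay(object, "missing")
  if (!is.logical(miss))
    msgs <- c(msgs, "'missing' assay must be logical")
  xs <- SummarizedExperiment::assay(object, "x")
  ys <- SummarizedExperiment::assay(object, "y")
  bad <- (!miss) & (!is.finite(xs) | !is.finite(ys))
  if (any(bad))
    msgs <- c(msgs, "non-missing coordinates must be finite")
  pos <- S4Vectors::metadata(object)$position
  if (is.null(pos) || !pos %in% c("lying", "sitting"))
    msgs <- c(msgs, "metadata position must be 'lying' or 'sitting'")
  if (length(msgs)) msgs else TRUE
})

#' ScoringConfig: pipeline tuning parameters
#'
#' Bundles the handful of parameters that govern preprocessing, feature
#' reduction and model evaluation. Defaults reproduce the reference protocol:
#' likelihood cutoff 0.8, sequences extended to 500 frames (20 s at 25 Hz),
#' 10 windows of 2 s, 5-fold subject-grouped cross-validation, 100-tree
#' random forest.
#'
#' @slot pCutoff likelihood threshold below which points are masked.
#' @slot targetLength frame count every sequence is extended to; must be a
#'   multiple of `nWindows`.
#' @slot nWindows number of equally sized time windows per feature trace.
#' @slot windowSeconds nominal window duration in seconds (documentation only;
#'   the window length in frames is `targetLength / nWindows`).
#' @slot nFolds folds for grouped cross-validation.
#' @slot nTrees trees in the random-forest regressor.
#' @slot seed integer driving fold shuffling and forest randomness.
#' @aliases ScoringConfig-class
#' @exportClass ScoringConfig
setClass("ScoringConfig",
  representation(pCutoff = "numeric", targetLength = "integer",
                 nWindows = "integer", windowSeconds = "numeric",
                 nFolds = "integer", nTrees = "integer", seed = "integer"))

setValidity("ScoringConfig", function(object) {
  msgs <- character()
  if (object@pCutoff < 0 || object@pCutoff > 1)
    msgs <- c(msgs, "pCutoff must lie in [0, 1]")
  if (object@targetLength < 1L || object@nWindows < 1L)
    msgs <- c(msgs, "targetLength and nWindows must be positive")
  else if (object@targetLength %% object@nWindows != 0L)
    msgs <- c(msgs, "targetLength must be divisible by nWindows")
  if (object@nFolds < 2L) msgs <- c(msgs, "nFolds must be at least 2")
  if (object@nTrees < 1L) msgs <- c(msgs, "nTrees must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @param pCutoff,targetLength,nWindows,windowSeconds,nFolds,nTrees,seed see slots.
#' @return `ScoringConfig()` returns a validated `ScoringConfig` object.
#' @examples
#' ScoringConfig()
#' ScoringConfig(pCutoff = 0.6, seed = 7L)
#' @rdname ScoringConfig-class
#' @export
ScoringConfig <- function(pCutoff = 0.8, targetLength = 500L, nWindows = 10L,
                          windowSeconds = 2, nFolds = 5L, nTrees = 100L,
                          seed = 42L) {
  new("ScoringConfig", pCutoff = as.numeric(pCutoff),
      targetLength = as.integer(targetLength), nWindows = as.integer(nWindows),
      windowSeconds = as.numeric(windowSeconds), nFolds = as.integer(nFolds),
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' @export
setMethod("show", "ScoringConfig", function(object) {
  cat("ScoringConfig\n",
      sprintf("  p-cutoff: %.2f | target length: %d frames | %d windows\n",
              object@pCutoff, object@targetLength, object@nWindows),
      sprintf("  CV: %d folds | forest: %d trees | seed: %d\n",
              object@nFolds, object@nTrees, object@seed), sep = "")
})

#' AgreementReport: inter-rater agreement on normalized DIS scores
#'
#' Returned by [interRaterMae()]. Holds the mean absolute error between two
#' raters' normalized amplitude scores on the videos they both scored, the
#' sample standard deviation of the absolute errors, the overlap size and a
#' 5x5 confusion matrix over the normalized levels {0, 0.25, 0.5, 0.75, 1}.
#'
#' @aliases AgreementReport-class
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(mae = "numeric", sd = "numeric", n = "integer",
                 confusion = "matrix", item = "character"))

setValidity("AgreementReport", function(object) {
  msgs <- character()
  if (object@mae < 0 || object@mae > 1) msgs <- c(msgs, "mae must lie in [0, 1]")
  if (sum(object@confusion) != object@n)
    msgs <- c(msgs, "confusion counts must sum to n")
  if (length(msgs)) msgs else TRUE
})

#' ModelReport: cross-validated model-vs-rater evaluation
#'
#' Returned by [crossValidate()]. Pools the out-of-fold predictions of the k
#' fold models so that every sample is predicted exactly once by a model that
#' never saw its subject, and summarises them as MAE, the sample SD of the
#' absolute errors, and a 5x5 confusion matrix of discretized predictions
#' against the rater's normalized scores.
#'
#' @slot raterId,item which rater/item the model was trained against.
#' @slot predictions per-sample data.frame: subject_id, video_id, side, fold,
#'   target, prediction, abs_error.
#' @slot mae,sd,n pooled error summary.
#' @slot confusion 5x5 count matrix (rows = rater level, cols = model level).
#' @slot foldSizes samples per fold.
#' @slot seed seed used for fold assignment and forests.
#' @aliases ModelReport-class
#' @exportClass ModelReport
setClass("ModelReport",
  representation(raterId = "character", item = "character",
                 predictions = "data.frame", mae = "numeric", sd = "numeric",
                 n = "integer", confusion = "matrix", foldSizes = "integer",
                 seed = "integer"))

setValidity("ModelReport", function(object) {
  msgs <- character()
  if (nrow(object@predictions) != object@n)
    msgs <- c(msgs, "predictions must have n rows")
  if (sum(object@foldSizes) != object@n)
    msgs <- c(msgs, "fold sizes must sum to n")
  if (object@mae < 0 || object@mae > 1) msgs <- c(msgs, "mae must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' TrackingEval: keypoint tracking accuracy against manual labels
#'
#' Returned by [trackingMae()]. The headline `mae` is the mean Euclidean pixel
#' distance between predicted and manually labeled points, unweighted across
#' all matched (frame, bodypart) pairs; a per-bodypart breakdown and the count
#' of points excluded by the likelihood cutoff are carried along.
#'
#' @aliases TrackingEval-class
#' @exportClass TrackingEval
setClass("TrackingEval",
  representation(mae = "numeric", perBodypart = "data.frame",
                 nUsed = "integer", nExcluded = "integer",
                 pCutoff = "numeric"))

#' SyntheticSpec: parameters of the stick-figure simulator
#'
#' Describes one synthetic recording condition: a base posture for the 12
#' landmarks inside the standardized 720x575-pixel frame, plus the dynamics of
#' the simulated dystonic movement. Distal landmarks drift slowly around the
#' base posture with an RMS excursion proportional to the severity level
#' (`amplitudePerLevel` pixels per DIS unit); all landmarks receive white pixel
#' jitter, and a small fraction of points is given a low tracker likelihood to
#' exercise the cutoff path.
#'
#' @slot position `"lying"` or `"sitting"`.
#' @slot basePosture 12x2 matrix (x, y) of resting landmark positions,
#'   rownames = [bodyPartNames()].
#' @slot amplitudePerLevel pixels of RMS excursion per severity unit.
#' @slot excursionTimescale smoothing timescale of the drift, seconds.
#' @slot jitterSd SD of per-coordinate white noise, pixels.
#' @slot dropoutRate fraction of points given likelihood below 0.8.
#' @slot nFrames,frameRate sequence length and sampling rate.
#' @slot frameSize video frame width and height in pixels.
#' @aliases SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(position = "character", basePosture = "matrix",
                 amplitudePerLevel = "numeric", excursionTimescale = "numeric",
                 jitterSd = "numeric", dropoutRate = "numeric",
                 nFrames = "integer", frameRate = "numeric",
                 frameSize = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (!object@position %in% c("lying", "sitting"))
    msgs <- c(msgs, "position must be 'lying' or 'sitting'")
  bp <- object@basePosture
  if (!identical(dim(bp), c(12L, 2L)) ||
      !identical(sort(rownames(bp)), sort(bodyPartNames())))
    msgs <- c(msgs, "basePosture must be a 12x2 matrix with canonical rownames")
  else {
    inFrame <- bp[, 1] >= 0 & bp[, 1] <= object@frameSize[1] &
               bp[, 2] >= 0 & bp[, 2] <= object@frameSize[2]
    if (!all(inFrame)) msgs <- c(msgs, "base posture must lie inside the frame")
  }
  if (object@amplitudePerLevel < 0)
    msgs <- c(msgs, "amplitudePerLevel must be non-negative")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msgs <- c(msgs, "dropoutRate must lie in [0, 1)")
  if (object@nFrames < 1L) msgs <- c(msgs, "nFrames must be positive")
  if (length(msgs)) msgs else TRUE
})
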