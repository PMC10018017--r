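#' Construct a PoseSequence
#'
#' Builds a [PoseSequence-class] from frame-by-landmark matrices. Inputs are in
#' the orientation keypoint tables are written in (one row per frame, one
#' column per landmark); they are stored internally landmark-by-frame.
#'
#' @param x,y numeric matrices, frames x 12 landmarks, with column names from
#'   [bodyPartNames()] (any order; reordered canonically).
#' @param likelihood matrix of tracker confidences in \[0, 1\]; defaults to 1.
#' @param missing logical matrix marking points to treat as absent; defaults to
#'   points with a non-finite coordinate.
#' @param videoId,subjectId identifiers carried through the pipeline.
#' @param position rest position of the recording, `"lying"` or `"sitting"`.
#' @param frameRate sampling rate in Hz.
#' @param frameSize integer width, height of the standardized video frame.
#' @return A validated `PoseSequence`.
#' @examples
#' n <- 10
#' xy <- matrix(100, n, 12, dimnames = list(NULL, bodyPartNames()))
#' ps <- PoseSequence(xy, xy + 50, videoId = "v1", subjectId = "s1",
#'                    position = "lying")
#' nFrames(ps)
#' @export
PoseSequence <- function(x, y, likelihood = NULL, missing = NULL,
                         videoId = "video", subjectId = "subject",
                         position = c("lying", "sitting"),
                         frameRate = 25, frameSize = c(720L, 575L)) {
  position <- match.arg(position)
  x <- as.matrix(x); y <- as.matrix(y)
  parts <- bodyPartNames()
  for (m in list(x, y)) {
    if (is.null(colnames(m)) || !all(parts %in% colnames(m)))
      stopf("coordinate matrices need columns for all 12 body parts")
  }
  if (nrow(x) < 1L) stopf("a PoseSequence needs at least one frame")
  if (!identical(dim(x), dim(y)))
    stopf("x and y matrices must have identical dimensions")
  x <- x[, parts, drop = FALSE]; y <- y[, parts, drop = FALSE]
  if (is.null(likelihood)) {
    likelihood <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  } else {
    likelihood <- as.matrix(likelihood)[, parts, drop = FALSE]
  }
  if (is.null(missing)) {
    missing <- !is.finite(x) | !is.finite(y)
  } else {
    missing <- as.matrix(missing)[, parts, drop = FALSE]
    storage.mode(missing) <- "logical"
    missing <- missing | !is.finite(x) | !is.finite(y)
  }
  rd <- S4Vectors::DataFrame(side = .partSide(parts),
                             segment = .partSegment(parts),
                             row.names = parts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = t(x), y = t(y), likelihood = t(likelihood),
                  missing = t(missing)),
    rowData = rd,
    metadata = list(videoId = as.character(videoId),
                    subjectId = as.character(subjectId),
                    position = position,
                    frameRate = as.numeric(frameRate),
                    frameSize = as.integer(frameSize)))
  new("PoseSequence", se)
}

# frames x parts view of an assay
.frameMatrix <- function(seq, what) t(SummarizedExperiment::assay(seq, what))

#' Accessors for PoseSequence objects
#'
#' `coordX()`, `coordY()`, `likelihoods()` and `missingMask()` return
#' frames x landmarks matrices; `landmarkTrack()` returns the n x 2 (x, y)
#' trajectory of one landmark; the remaining accessors expose video-level
#' metadata.
#'
#' @param x a [PoseSequence-class] (or report object for the shared generics).
#' @param part canonical landmark name, e.g. `"left_knee"`.
#' @name PoseSequence-accessors
#' @aliases videoId subjectId posePosition frameRate frameSize nFrames coordX
#'   coordY likelihoods missingMask landmarkTrack
#' @examples
#' spec <- syntheticSpec("lying")
#' ps <- simulatePoseSequence(spec, levelLeft = 2, levelRight = 1, seed = 1)
#' dim(coordX(ps))
#' head(landmarkTrack(ps, "left_ankle"))
NULL

#' @rdname PoseSequence-accessors
#' @export
setMethod("videoId", "PoseSequence",
          function(x) S4Vectors::metadata(x)$videoId)

#' @rdname PoseSequence-accessors
#' @export
setMethod("subjectId", "PoseSequence",
          function(x) S4Vectors::metadata(x)$subjectId)

#' @rdname PoseSequence-accessors
#' @export
setMethod("posePosition", "PoseSequence",
          function(x) S4Vectors::metadata(x)$position)

#' @rdname PoseSequence-accessors
#' @export
setMethod("frameRate", "PoseSequence",
          function(x) S4Vectors::metadata(x)$frameRate)

#' @rdname PoseSequence-accessors
#' @export
setMethod("frameSize", "PoseSequence",
          function(x) S4Vectors::metadata(x)$frameSize)

#' @rdname PoseSequence-accessors
#' @export
setMethod("nFrames", "PoseSequence", function(x) ncol(x))

#' @rdname PoseSequence-accessors
#' @export
setMethod("coordX", "PoseSequence", function(x) .frameMatrix(x, "x"))

#' @rdname PoseSequence-accessors
#' @export
setMethod("coordY", "PoseSequence", function(x) .frameMatrix(x, "y"))

#' @rdname PoseSequence-accessors
#' @export
setMethod("likelihoods", "PoseSequence",
          function(x) .frameMatrix(x, "likelihood"))

#' @rdname PoseSequence-accessors
#' @export
setMethod("missingMask", "PoseSequence", function(x) .frameMatrix(x, "missing"))

#' @rdname PoseSequence-accessors
#' @export
setMethod("landmarkTrack", "PoseSequence", function(x, part) {
  if (!part %in% bodyPartNames()) stopf("unknown body part '%s'", part)
  cbind(x = SummarizedExperiment::assay(x, "x")[part, ],
        y = SummarizedExperiment::assay(x, "y")[part, ])
})

#' @export
setMethod("show", "PoseSequence", function(object) {
  md <- S4Vectors::metadata(object)
  nmiss <- sum(SummarizedExperiment::assay(object, "missing"))
  cat(sprintf("PoseSequence '%s' (subject %s, %s)\n",
              md$videoId, md$subjectId, md$position),
      sprintf("  %d frames @ %g Hz, %dx%d px, 12 landmarks\n",
              ncol(object), md$frameRate, md$frameSize[1], md$frameSize[2]),
      sprintf("  %d masked points (%.1f%%)\n", nmiss,
              100 * nmiss / (12 * ncol(object))), sep = "")
})

# replace assays while preserving metadata; inputs frames x parts
.replaceAssays <- function(seq, x = NULL, y = NULL, likelihood = NULL,
                           missing = NULL) {
  md <- S4Vectors::metadata(seq)
  PoseSequence(
    x = if (is.null(x)) coordX(seq) else x,
    y = if (is.null(y)) coordY(seq) else y,
    likelihood = if (is.null(likelihood)) likelihoods(seq) else likelihood,
    missing = if (is.null(missing)) missingMask(seq) else missing,
    videoId = md$videoId, subjectId = md$subjectId, position = md$position,
    frameRate = md$frameRate, frameSize = md$frameSize)
}
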