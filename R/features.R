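# The three per-frame posture features and their windowed-median reduction.
#
# All three features are invariant under rigid transforms and reflection of
# the image plane, which is what makes the left/right sides of the body
# interchangeable as samples.

#' Distance to the landmark's whole-video mean position
#'
#' For each frame, the Euclidean pixel distance between the landmark and the
#' mean of its position over the entire (extrapolated) sequence. A landmark
#' that never moves yields an all-zero trace.
#'
#' @param track n x 2 matrix of (x, y) positions, no missing values.
#' @return Numeric vector of length n, all values >= 0.
#' @export
distanceToMiddlePoint <- function(track) {
  track <- as.matrix(track)
  if (nrow(track) < 1L) stopf("track needs at least one frame")
  if (any(!is.finite(track)))
    stopf("track contains missing points; interpolate before computing features")
  ctr <- colMeans(track)
  sqrt((track[, 1] - ctr[1])^2 + (track[, 2] - ctr[2])^2)
}

#' Perpendicular distance from a point to a line
#'
#' Distance from `point` to the infinite line through `lineA` and `lineB`
#' (the shoulder-hip bodyline in this pipeline). All arguments may be n x 2
#' matrices for per-frame evaluation; the line is degenerate, and an error is
#' raised naming the frame, if the two defining points coincide.
#'
#' @param point,lineA,lineB length-2 (x, y) vectors or n x 2 matrices.
#' @return Non-negative distance(s) in pixels.
#' @export
distanceToLine <- function(point, lineA, lineB) {
  toMat <- function(v) if (is.matrix(v)) v else matrix(v, 1L, 2L)
  p <- toMat(point); a <- toMat(lineA); b <- toMat(lineB)
  n <- max(nrow(p), nrow(a), nrow(b))
  rep2 <- function(m) if (nrow(m) == n) m else m[rep(1L, n), , drop = FALSE]
  p <- rep2(p); a <- rep2(a); b <- rep2(b)
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0))
    stopf("degenerate bodyline (identical endpoints) at frame %d",
          which(len == 0)[1])
  d <- abs(dx * (p[, 2] - a[, 2]) - dy * (p[, 1] - a[, 1])) / len
  if (length(d) == 1L) as.numeric(d) else d
}

#' Interior joint angle from three keypoints
#'
#' The angle at `vertex` between the rays towards `a` and `c`, in degrees in
#' \[0, 180\]. The cosine is clamped to \[-1, 1\] before `acos` to absorb
#' floating-point overshoot. Being a 2D projection of the true joint angle, it
#' carries a camera-angle projection error which is accepted, not corrected.
#'
#' @param a,vertex,c length-2 (x, y) vectors or n x 2 matrices (e.g. wrist,
#'   elbow, shoulder for the elbow angle).
#' @return Angle(s) in degrees.
#' @export
jointAngle <- function(a, vertex, c) {
  toMat <- function(v) if (is.matrix(v)) v else matrix(v, 1L, 2L)
  a <- toMat(a); v <- toMat(vertex); cc <- toMat(c)
  n <- max(nrow(a), nrow(v), nrow(cc))
  rep2 <- function(m) if (nrow(m) == n) m else m[rep(1L, n), , drop = FALSE]
  a <- rep2(a); v <- rep2(v); cc <- rep2(cc)
  u1 <- a - v; u2 <- cc - v
  l1 <- sqrt(rowSums(u1^2)); l2 <- sqrt(rowSums(u2^2))
  if (any(l1 == 0 | l2 == 0))
    stopf("zero-length limb vector at frame %d", which(l1 == 0 | l2 == 0)[1])
  cosang <- pmin(1, pmax(-1, rowSums(u1 * u2) / (l1 * l2)))
  ang <- acos(cosang) * 180 / pi
  if (length(ang) == 1L) as.numeric(ang) else ang
}

#' Reduce a per-frame trace to window medians
#'
#' Splits the trace into `nWindows` equally sized contiguous blocks and takes
#' the median of each (even-length windows: mean of the two central order
#' statistics). The trace length must be divisible by `nWindows`; extrapolate
#' the sequence first if it is not.
#'
#' @param trace numeric vector of per-frame values.
#' @param nWindows number of windows (default 10).
#' @return Numeric vector of length `nWindows`.
#' @examples
#' windowedMedian(rep(5, 500), 10)
#' @export
windowedMedian <- function(trace, nWindows = 10L) {
  nWindows <- as.integer(nWindows)
  if (length(trace) %% nWindows != 0L)
    stopf("trace length %d is not divisible by %d windows; extrapolate first",
          length(trace), nWindows)
  apply(matrix(trace, ncol = nWindows), 2L, stats::median)
}

# position-specific feature plan: which landmarks feed each feature family
.featurePlan <- function(position) {
  if (position == "sitting") {
    list(d2m = c("wrist", "elbow", "shoulder"),
         d2l = c("wrist", "elbow"),
         angle = c("wrist", "elbow", "shoulder"))  # a, vertex, c
  } else {
    list(d2m = c("ankle", "knee", "hip"),
         d2l = c("ankle", "knee"),
         angle = c("ankle", "knee", "hip"))
  }
}

#' Assemble the 60-value feature vector for one body side
#'
#' Computes the three per-frame posture features for the side's landmarks --
#' distance-to-middle-point for three landmarks, distance to the same-side
#' shoulder-hip bodyline for two, and one joint angle -- and reduces each of
#' the six traces to `nWindows` window medians. The landmark sets depend on
#' the rest position: sitting uses wrist/elbow/shoulder with the elbow angle,
#' lying uses ankle/knee/hip with the knee angle. The fixed output order is
#' the three d2m blocks, the two d2l blocks, then the angle block.
#'
#' @param seq a preprocessed [PoseSequence-class] of exactly
#'   `config@targetLength` complete frames.
#' @param side `"left"` or `"right"`.
#' @param config a [ScoringConfig-class].
#' @return Named numeric vector of length `6 * config@nWindows` (60 by
#'   default), names like `d2m_wrist_w01`.
#' @export
buildSampleFeatures <- function(seq, side = c("left", "right"),
                                config = ScoringConfig()) {
  side <- match.arg(side)
  stopifnot(is(seq, "PoseSequence"))
  if (nFrames(seq) != config@targetLength)
    stopf("sequence has %d frames but config expects %d; run preprocessPose()",
          nFrames(seq), config@targetLength)
  if (any(missingMask(seq)))
    stopf("sequence still has masked points on side '%s'; interpolate first",
          side)
  plan <- .featurePlan(posePosition(seq))
  trk <- function(segment) landmarkTrack(seq, paste(side, segment, sep = "_"))

  shoulder <- trk("shoulder"); hip <- trk("hip")
  traces <- list()
  for (s in plan$d2m)
    traces[[paste0("d2m_", s)]] <- distanceToMiddlePoint(trk(s))
  for (s in plan$d2l)
    traces[[paste0("d2l_", s)]] <- distanceToLine(trk(s), shoulder, hip)
  traces[[paste0("angle_", plan$angle[2])]] <-
    jointAngle(trk(plan$angle[1]), trk(plan$angle[2]), trk(plan$angle[3]))

  out <- unlist(lapply(traces, windowedMedian, nWindows = config@nWindows))
  names(out) <- as.vector(vapply(names(traces), function(nm)
    sprintf("%s_w%02d", nm, seq_len(config@nWindows)),
    character(config@nWindows)))
  out
}

#' Split a video into its two side samples
#'
#' The feature set is symmetric in the body's vertical axis, so each video
#' contributes two samples: the left-side and right-side feature vectors,
#' sharing the video's identifiers. Returns a one-video feature table in the
#' same layout as [featureTable()].
#'
#' @param seq a preprocessed [PoseSequence-class].
#' @param config a [ScoringConfig-class].
#' @return A data.frame with two rows (left, right): `video_id`, `subject_id`,
#'   `position`, `side`, then the feature columns.
#' @export
splitSides <- function(seq, config = ScoringConfig()) {
  rows <- lapply(c("left", "right"), function(side) {
    fv <- tryCatch(buildSampleFeatures(seq, side, config),
                   error = function(e)
                     stopf("side '%s' of video '%s': %s", side, videoId(seq),
                           conditionMessage(e)))
    cbind(data.frame(video_id = videoId(seq), subjectId = subjectId(seq),
                     position = posePosition(seq), side = side,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "subjectId"] <- "subject_id"
  rownames(out) <- NULL
  out
}

#' Feature table for a list of sequences
#'
#' Preprocesses each sequence (unless `preprocess = FALSE`) and stacks the
#' two per-side samples of every video into one table.
#'
#' @param seqs list of [PoseSequence-class] objects.
#' @param config a [ScoringConfig-class].
#' @param preprocess run [preprocessPose()] on each sequence first.
#' @return data.frame, two rows per video.
#' @export
featureTable <- function(seqs, config = ScoringConfig(), preprocess = TRUE) {
  rows <- lapply(seqs, function(s) {
    if (preprocess) s <- preprocessPose(s, config)
    splitSides(s, config)
  })
  do.call(rbind, rows)
}

# columns of a sample/feature table that are not features
.metaCols <- c("video_id", "subject_id", "position", "side", "rater_id",
               "item", "target", "fold")

featureColumns <- function(tab) setdiff(names(tab), .metaCols)

#' Export a feature table with a column dictionary
#'
#' Writes the feature matrix as flat CSV with generic column codes
#' `f00..f59` and a YAML sidecar (`<path>.dict.yaml`) mapping each code to
#' its descriptive name.
#'
#' @param tab a feature table from [featureTable()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(tab, path) {
  fcols <- featureColumns(tab)
  codes <- sprintf("f%02d", seq_along(fcols) - 1L)
  out <- tab
  names(out)[match(fcols, names(out))] <- codes
  utils::write.csv(out, path, row.names = FALSE)
  yaml::write_yaml(stats::setNames(as.list(fcols), codes),
                   paste0(path, ".dict.yaml"))
  invisible(path)
}
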