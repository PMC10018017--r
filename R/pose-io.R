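# Keypoint table import/export.
#
# Two CSV dialects are supported:
#  * the three-header-row layout written by common markerless trackers
#    (scorer / bodyparts / coords rows, a leading frame-index column, then
#    x, y, likelihood triplets per bodypart);
#  * a flat single-header layout with columns <side>_<segment>_{x,y,p}.
# Masked points are serialized as empty x/y cells and restored on read.

.parseNumericCells <- function(chr, rowIdx, colLabel) {
  chr[chr == ""] <- NA_character_
  num <- suppressWarnings(as.numeric(chr))
  bad <- which(!is.na(chr) & is.na(num))
  if (length(bad))
    stopf("non-numeric value '%s' at row %d, column '%s'",
          chr[bad[1]], rowIdx[bad[1]], colLabel)
  num
}

.readDlcDialect <- function(path) {
  hdr <- readLines(path, n = 3L)
  split <- lapply(hdr, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  bodyparts <- split[[2]][-1]
  coords <- split[[3]][-1]
  raw <- utils::read.csv(path, skip = 3L, header = FALSE,
                         colClasses = "character")
  if (ncol(raw) != length(bodyparts) + 1L)
    stopf("malformed keypoint table '%s': header/data width mismatch", path)
  list(bodyparts = bodyparts, coords = coords,
       frames = raw[[1]], cells = raw[, -1, drop = FALSE])
}

.readFlatDialect <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  cols <- setdiff(names(raw), "frame")
  m <- regmatches(cols, regexec("^(.*)_(x|y|p|likelihood)$", cols))
  ok <- lengths(m) == 3L
  if (!all(ok)) stopf("unrecognized column(s): %s",
                      paste(cols[!ok], collapse = ", "))
  list(bodyparts = vapply(m, `[`, "", 2L),
       coords = sub("^p$", "likelihood", vapply(m, `[`, "", 3L)),
       frames = if ("frame" %in% names(raw)) raw[["frame"]]
                else as.character(seq_len(nrow(raw)) - 1L),
       cells = raw[, cols, drop = FALSE])
}

#' Read a keypoint table
#'
#' Imports one video's tracked landmark coordinates into a
#' [PoseSequence-class]. Columns for the 12 canonical landmarks are required;
#' columns for any other tracked bodypart (e.g. a nose marker) are ignored
#' with a warning. Empty x/y cells become masked points.
#'
#' @param path CSV file in either supported dialect.
#' @param videoId,subjectId identifiers to attach.
#' @param position rest position, `"lying"` or `"sitting"`.
#' @param frameRate,frameSize sequence metadata (defaults: 25 Hz, 720x575).
#' @return A [PoseSequence-class].
#' @seealso [writePoseTable()]
#' @export
readPoseTable <- function(path, videoId, subjectId,
                          position = c("lying", "sitting"),
                          frameRate = 25, frameSize = c(720L, 575L)) {
  position <- match.arg(position)
  if (!file.exists(path)) stopf("keypoint table '%s' does not exist", path)
  first <- readLines(path, n = 1L)
  dlc <- grepl("^scorer[,;]", first)
  tab <- if (dlc) .readDlcDialect(path) else .readFlatDialect(path)

  parts <- bodyPartNames()
  known <- tab$bodyparts %in% parts
  extra <- setdiff(unique(tab$bodyparts[!known]), character())
  if (length(extra))
    warnf("ignoring unknown bodypart column(s): %s",
          paste(extra, collapse = ", "))
  nF <- nrow(tab$cells)
  if (nF < 1L) stopf("keypoint table '%s' has no frames", path)
  ord <- order(.parseNumericCells(tab$frames, seq_len(nF), "frame"))

  get <- function(part, coord) {
    j <- which(tab$bodyparts == part & tab$coords == coord)
    if (length(j) != 1L)
      stopf("keypoint table '%s' lacks a '%s' column for bodypart '%s'",
            path, coord, part)
    .parseNumericCells(tab$cells[[j]], seq_len(nF),
                       paste(part, coord, sep = "_"))[ord]
  }
  x <- vapply(parts, get, numeric(nF), coord = "x")
  y <- vapply(parts, get, numeric(nF), coord = "y")
  p <- vapply(parts, get, numeric(nF), coord = "likelihood")
  PoseSequence(x, y, likelihood = p, videoId = videoId, subjectId = subjectId,
               position = position, frameRate = frameRate,
               frameSize = frameSize)
}

#' Write a keypoint table
#'
#' Serializes a [PoseSequence-class] in the three-header-row tracker dialect.
#' Masked points are written as empty x/y cells so that
#' `readPoseTable(writePoseTable(seq))` reproduces coordinates, likelihoods
#' and the missing mask exactly.
#'
#' @param seq a valid `PoseSequence` with at least one frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePoseTable <- function(seq, path) {
  stopifnot(is(seq, "PoseSequence"))
  validObject(seq)
  parts <- bodyPartNames()
  x <- coordX(seq); y <- coordY(seq); p <- likelihoods(seq)
  miss <- missingMask(seq)
  x[miss] <- NA_real_; y[miss] <- NA_real_
  fmt <- function(m) {
    out <- format(m, digits = 17, trim = TRUE, scientific = FALSE)
    out[is.na(m)] <- ""
    out
  }
  n <- nFrames(seq)
  body <- matrix("", n, 3L * length(parts))
  for (k in seq_along(parts)) {
    body[, 3L * k - 2L] <- fmt(x[, k])
    body[, 3L * k - 1L] <- fmt(y[, k])
    body[, 3L * k] <- fmt(p[, k])
  }
  lines <- c(
    paste(c("scorer", rep("dyskscore", 3L * length(parts))), collapse = ","),
    paste(c("bodyparts", rep(parts, each = 3L)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
          collapse = ","),
    paste(seq_len(n) - 1L, apply(body, 1L, paste, collapse = ","), sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stopf("cannot write '%s': %s", path,
                                           conditionMessage(e)))
  invisible(path)
}

#' Mask low-likelihood points
#'
#' Marks every point whose tracker likelihood falls below `cutoff` as missing;
#' points at or above the cutoff are untouched (the boundary keeps the point,
#' matching the common tracker convention). Coordinates are never altered, so
#' the operation is idempotent and monotone in `cutoff`.
#'
#' @param seq a [PoseSequence-class].
#' @param cutoff likelihood threshold in \[0, 1\].
#' @return A `PoseSequence` with an updated missing mask.
#' @export
applyLikelihoodCutoff <- function(seq, cutoff = 0.8) {
  stopifnot(is(seq, "PoseSequence"))
  .assertScalarNumber(cutoff, "cutoff")
  if (cutoff < 0 || cutoff > 1) stopf("cutoff must lie in [0, 1]")
  miss <- missingMask(seq) | (likelihoods(seq) < cutoff)
  .replaceAssays(seq, missing = miss)
}

#' Fill masked points by interpolation
#'
#' Interior runs of missing points are filled by per-coordinate linear
#' interpolation between the flanking observed frames; leading and trailing
#' runs hold the nearest observed value. Observed points are left bit-exact.
#' Every landmark must have at least two observed frames.
#'
#' @param seq a [PoseSequence-class].
#' @return A `PoseSequence` with no missing points.
#' @export
interpolateGaps <- function(seq) {
  stopifnot(is(seq, "PoseSequence"))
  x <- coordX(seq); y <- coordY(seq); miss <- missingMask(seq)
  n <- nrow(x)
  for (part in colnames(x)) {
    m <- miss[, part]
    if (!any(m)) next
    obs <- which(!m)
    if (length(obs) < 2L)
      stopf("landmark '%s' has fewer than 2 usable frames; cannot interpolate",
            part)
    idx <- which(m)
    x[idx, part] <- stats::approx(obs, x[obs, part], xout = idx,
                                  rule = 2)$y
    y[idx, part] <- stats::approx(obs, y[obs, part], xout = idx,
                                  rule = 2)$y
  }
  .replaceAssays(seq, x = x, y = y,
                 missing = matrix(FALSE, n, ncol(x), dimnames = dimnames(x)))
}

#' Extend a sequence to a fixed length by cyclic tiling
#'
#' Short recordings are brought to the common analysis length by repeating the
#' existing frames in order: output frame `i` equals input frame `i mod n`.
#' Inputs already at the target length pass through unchanged; longer inputs
#' are refused (truncation must be an explicit, separate choice).
#'
#' @param seq a [PoseSequence-class].
#' @param target desired frame count.
#' @return A `PoseSequence` with exactly `target` frames.
#' @export
extrapolateToLength <- function(seq, target = 500L) {
  stopifnot(is(seq, "PoseSequence"))
  target <- as.integer(target)
  n <- nFrames(seq)
  if (n > target)
    stopf("sequence has %d frames, longer than target %d; refusing to truncate",
          n, target)
  if (n == target) return(seq)
  idx <- ((seq_len(target) - 1L) %% n) + 1L
  .replaceAssays(seq,
                 x = coordX(seq)[idx, , drop = FALSE],
                 y = coordY(seq)[idx, , drop = FALSE],
                 likelihood = likelihoods(seq)[idx, , drop = FALSE],
                 missing = missingMask(seq)[idx, , drop = FALSE])
}

#' Standard preprocessing chain
#'
#' Applies, in order: likelihood cutoff, gap interpolation, cyclic
#' extrapolation to `targetLength(config)`. Features must see a complete,
#' fixed-length sequence, which this guarantees.
#'
#' @param seq a [PoseSequence-class].
#' @param config a [ScoringConfig-class].
#' @return A complete `PoseSequence` of `config@targetLength` frames.
#' @export
preprocessPose <- function(seq, config = ScoringConfig()) {
  seq <- applyLikelihoodCutoff(seq, config@pCutoff)
  seq <- interpolateGaps(seq)
  extrapolateToLength(seq, config@targetLength)
}
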