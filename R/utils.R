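# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.bodySides <- c("left", "right")
.bodySegments <- c("wrist", "elbow", "shoulder", "hip", "knee", "ankle")

#' Canonical body-landmark names
#'
#' The stick figure tracks 12 landmarks: wrist, elbow, shoulder, hip, knee and
#' ankle on each body side. Names are `<side>_<segment>` in a fixed order
#' (all left, then all right) used throughout the package.
#'
#' @return Character vector of length 12.
#' @examples
#' bodyPartNames()
#' @export
bodyPartNames <- function() {
  paste(rep(.bodySides, each = length(.bodySegments)),
        rep(.bodySegments, times = length(.bodySides)), sep = "_")
}

# side/segment lookup for a vector of canonical names
.partSide <- function(parts) sub("_.*$", "", parts)
.partSegment <- function(parts) sub("^[^_]*_", "", parts)

# The five normalized DIS amplitude levels.
.disLevels <- c(0, 0.25, 0.5, 0.75, 1)

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}
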