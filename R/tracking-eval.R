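# Tracking accuracy of predicted keypoints against manual labels.

#' Mean Euclidean tracking error
#'
#' Matches predicted keypoints to manual labels on (video_id, frame, bodypart)
#' and reports the mean Euclidean pixel distance across all matched points --
#' unweighted over bodyparts and frames -- optionally after excluding
#' predictions whose likelihood falls below `pCutoff`. A per-bodypart
#' breakdown and the number of excluded points are included.
#'
#' @param pred data.frame of predictions: `video_id, frame, bodypart, x, y,
#'   likelihood`.
#' @param labels data.frame of manual labels: `video_id, frame, bodypart, x, y`.
#' @param pCutoff optional likelihood threshold; `NULL` evaluates all matches.
#' @return A [TrackingEval-class].
#' @examples
#' lab <- data.frame(video_id = "v", frame = 1, bodypart = "left_wrist",
#'                   x = 0, y = 0)
#' prd <- transform(lab, x = 3, y = 4, likelihood = 0.9)
#' mae(trackingMae(prd, lab))   # 5
#' @export
trackingMae <- function(pred, labels, pCutoff = NULL) {
  needP <- c("video_id", "frame", "bodypart", "x", "y", "likelihood")
  needL <- c("video_id", "frame", "bodypart", "x", "y")
  if (!all(needP %in% names(pred)))
    stopf("pred needs columns %s", paste(needP, collapse = ", "))
  if (!all(needL %in% names(labels)))
    stopf("labels needs columns %s", paste(needL, collapse = ", "))
  m <- merge(labels, pred, by = c("video_id", "frame", "bodypart"),
             suffixes = c("_label", "_pred"))
  if (nrow(m) == 0L) stopf("no (video, frame, bodypart) keys match")
  if (any(m$likelihood < 0 | m$likelihood > 1, na.rm = TRUE))
    stopf("likelihoods must lie in [0, 1]")
  keep <- if (is.null(pCutoff)) rep(TRUE, nrow(m)) else m$likelihood >= pCutoff
  if (!any(keep)) stopf("no points remain after applying the p-cutoff")
  d <- sqrt((m$x_pred - m$x_label)^2 + (m$y_pred - m$y_label)^2)
  per <- stats::aggregate(list(mae = d[keep]),
                          by = list(bodypart = m$bodypart[keep]), FUN = mean)
  per$n <- as.vector(table(m$bodypart[keep])[per$bodypart])
  new("TrackingEval", mae = mean(d[keep]), perBodypart = per,
      nUsed = sum(keep), nExcluded = sum(!keep),
      pCutoff = if (is.null(pCutoff)) NA_real_ else pCutoff)
}

#' Convert a pixel error to centimetres
#'
#' The standardized 720x575 video frame covers roughly 3 x 2 m, i.e. an image
#' resolution of 0.4 cm per pixel. The product is reported to one decimal.
#'
#' @param maePixels error in pixels.
#' @param cmPerPixel image resolution (cm per pixel), default 0.4.
#' @return Error in cm, rounded to one decimal.
#' @examples
#' pixelsToCm(10)     # 4
#' pixelsToCm(4.49)   # 1.8
#' @export
pixelsToCm <- function(maePixels, cmPerPixel = 0.4) {
  if (!is.numeric(cmPerPixel) || cmPerPixel <= 0)
    stopf("cmPerPixel must be positive")
  round(maePixels * cmPerPixel, 1)
}
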