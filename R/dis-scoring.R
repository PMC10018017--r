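# Clinical DIS amplitude scores: normalization, agreement, discretization.
#
# A score table is a data.frame with columns video_id, rater_id, item
# ("arm_amplitude" or "leg_amplitude"), side ("left"/"right") and raw
# (integer 0..4). Normalized scores (raw / 4) are always computed on the fly,
# never stored.

.scoreItems <- c("arm_amplitude", "leg_amplitude")

#' Normalize a raw DIS amplitude score
#'
#' Divides the raw item score by the maximum attainable score, mapping the
#' 0..4 amplitude scale onto the percentage-of-range levels
#' {0, 0.25, 0.50, 0.75, 1}.
#'
#' @param raw integer score(s), 0..`maxRaw`.
#' @param maxRaw maximum possible score on the item (4 for amplitude).
#' @return `raw / maxRaw`.
#' @examples
#' normalizeScore(2)      # 0.5
#' normalizeScore(0:4)
#' @export
normalizeScore <- function(raw, maxRaw = 4L) {
  if (maxRaw <= 0) stopf("maxRaw must be positive")
  if (any(!is.finite(raw)) || any(raw != round(raw)) ||
      any(raw < 0 | raw > maxRaw))
    stopf("raw scores must be integers in 0..%d", maxRaw)
  raw / maxRaw
}

.validateScoreTable <- function(tab) {
  needed <- c("video_id", "rater_id", "item", "side", "raw")
  if (!all(needed %in% names(tab)))
    stopf("score table needs columns %s", paste(needed, collapse = ", "))
  if (!all(tab$item %in% .scoreItems))
    stopf("item must be one of %s", paste(.scoreItems, collapse = ", "))
  if (!all(tab$side %in% .bodySides))
    stopf("side must be 'left' or 'right'")
  normalizeScore(tab$raw)  # range check
  key <- paste(tab$video_id, tab$rater_id, tab$item, tab$side)
  if (anyDuplicated(key))
    stopf("duplicated score for key: %s", key[anyDuplicated(key)])
  invisible(tab)
}

#' Read / write a DIS score table
#'
#' CSV with columns `video_id, rater_id, item, side, raw`; raw scores are
#' validated as integers 0..4 with at most one score per
#' (video, rater, item, side).
#'
#' @param path CSV path.
#' @return `readScoreTable()` returns the validated data.frame.
#' @export
readScoreTable <- function(path) {
  if (!file.exists(path)) stopf("score table '%s' does not exist", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(video_id = "character",
                                        rater_id = "character"))
  .validateScoreTable(tab)
  tab
}

#' @param tab a score table.
#' @rdname readScoreTable
#' @export
writeScoreTable <- function(tab, path) {
  .validateScoreTable(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Snap a continuous prediction onto the five normalized levels
#'
#' Clamps into \[0, 1\], then returns the nearest of
#' {0, 0.25, 0.50, 0.75, 1}; exact midpoints round toward the lower
#' (clinically conservative) level. Idempotent on the levels themselves.
#'
#' @param value finite numeric vector of continuous scores.
#' @return Vector of normalized levels.
#' @examples
#' discretizePrediction(c(0.6, 0.375, 1.2))
#' @export
discretizePrediction <- function(value) {
  if (any(!is.finite(value))) stopf("predictions must be finite")
  v <- pmin(1, pmax(0, value))
  .disLevels[vapply(v, function(z) which.min(abs(z - .disLevels)), 1L)]
}

.levelFactor <- function(x) factor(x, levels = .disLevels)

#' 5x5 confusion matrix over normalized levels
#'
#' Rows are the reference levels, columns the discretized predictions; counts
#' sum to the number of samples and the diagonal holds exact agreements.
#'
#' @param truth vector of normalized levels (multiples of 0.25 in \[0, 1\]).
#' @param pred vector of continuous scores, discretized internally.
#' @return 5x5 integer matrix with level dimnames.
#' @export
confusionMatrix5 <- function(truth, pred) {
  if (length(truth) != length(pred))
    stopf("truth and pred must have equal length")
  if (length(truth) < 1L) stopf("empty input")
  if (!all(truth %in% .disLevels))
    stopf("truth values must be normalized levels 0, 0.25, 0.5, 0.75, 1")
  m <- table(truth = .levelFactor(truth),
             prediction = .levelFactor(discretizePrediction(pred)))
  unclass(as.matrix(m))
}

# shared MAE/SD summary over paired normalized scores
.absErrorSummary <- function(a, b) {
  err <- abs(a - b)
  list(mae = mean(err),
       sd = if (length(err) > 1L) stats::sd(err) else 0,
       n = length(err))
}

#' Inter-rater agreement on one DIS item
#'
#' Computes the mean absolute error between two raters' normalized amplitude
#' scores over the (video, side) keys both raters scored, together with the
#' sample SD of the absolute errors and the level confusion matrix. The
#' operation is symmetric in its arguments (up to transposition of the
#' confusion matrix).
#'
#' @param a,b score tables, each containing one rater's scores (extra raters
#'   may be present; supply `raterA`/`raterB` to select).
#' @param item `"arm_amplitude"` or `"leg_amplitude"`.
#' @param raterA,raterB optional rater ids to filter `a` and `b` by.
#' @return An [AgreementReport-class].
#' @export
interRaterMae <- function(a, b, item = c("arm_amplitude", "leg_amplitude"),
                          raterA = NULL, raterB = NULL) {
  item <- match.arg(item)
  .validateScoreTable(a); .validateScoreTable(b)
  if (!is.null(raterA)) a <- a[a$rater_id == raterA, , drop = FALSE]
  if (!is.null(raterB)) b <- b[b$rater_id == raterB, , drop = FALSE]
  a <- a[a$item == item, , drop = FALSE]
  b <- b[b$item == item, , drop = FALSE]
  m <- merge(a, b, by = c("video_id", "side"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L)
    stopf("raters share no scored (video, side) keys for item '%s'", item)
  na <- normalizeScore(m$raw_a); nb <- normalizeScore(m$raw_b)
  s <- .absErrorSummary(na, nb)
  new("AgreementReport", mae = s$mae, sd = s$sd, n = as.integer(s$n),
      confusion = confusionMatrix5(na, nb), item = item)
}
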