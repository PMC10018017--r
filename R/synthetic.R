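# Synthetic stick-figure cohorts with known severity ground truth.
#
# The simulator emulates the recording conditions of the scoring protocol:
# 25 Hz sequences of 500 frames in a 720x575-pixel frame, 12 landmarks, a
# lying or sitting rest posture, slow sustained excursions of the distal
# landmarks whose RMS amplitude grows linearly with the 0-4 severity level,
# white pixel jitter, and occasional low-likelihood dropouts. It makes every
# pipeline stage testable without clinical data; it does not attempt
# biomechanical realism or choreoathetotic dynamics.

.defaultBasePosture <- function(position) {
  parts <- bodyPartNames()
  bp <- matrix(NA_real_, 12L, 2L, dimnames = list(parts, c("x", "y")))
  if (position == "lying") {
    # supine, head towards image left; body axis at y = 290
    xs <- c(wrist = 305, elbow = 265, shoulder = 230, hip = 380,
            knee = 470, ankle = 550)
    off <- c(wrist = 35, elbow = 25, shoulder = 15, hip = 15,
             knee = 22, ankle = 30)
    for (seg in names(xs)) {
      bp[paste0("left_", seg), ] <- c(xs[seg], 290 + off[seg])
      bp[paste0("right_", seg), ] <- c(xs[seg], 290 - off[seg])
    }
  } else {
    # supported sitting, facing the camera; body axis at x = 360
    ys <- c(wrist = 315, elbow = 255, shoulder = 190, hip = 330,
            knee = 345, ankle = 460)
    off <- c(wrist = 60, elbow = 55, shoulder = 45, hip = 35,
             knee = 55, ankle = 50)
    for (seg in names(ys)) {
      bp[paste0("left_", seg), ] <- c(360 + off[seg], ys[seg])
      bp[paste0("right_", seg), ] <- c(360 - off[seg], ys[seg])
    }
  }
  bp
}

#' Build a synthetic recording specification
#'
#' @param position `"lying"` or `"sitting"`.
#' @param basePosture optional 12x2 landmark matrix; a plausible resting
#'   posture for the position is used by default.
#' @param amplitudePerLevel RMS excursion in pixels per severity unit
#'   (default 25; DIS amplitude is a percentage-of-range score, so the
#'   kinematic mapping is linear in the level).
#' @param excursionTimescale drift smoothing timescale in seconds (default 3,
#'   slow enough to read as sustained posturing rather than jitter).
#' @param jitterSd tracker noise SD in pixels (default 1.5).
#' @param dropoutRate fraction of points given likelihood below 0.8
#'   (default 0.02).
#' @param nFrames,frameRate sequence length (500) and rate (25 Hz).
#' @param frameSize frame width, height in pixels (720 x 575).
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(position = c("lying", "sitting"), basePosture = NULL,
                          amplitudePerLevel = 25, excursionTimescale = 3,
                          jitterSd = 1.5, dropoutRate = 0.02, nFrames = 500L,
                          frameRate = 25, frameSize = c(720L, 575L)) {
  position <- match.arg(position)
  if (is.null(basePosture)) basePosture <- .defaultBasePosture(position)
  new("SyntheticSpec", position = position, basePosture = basePosture,
      amplitudePerLevel = as.numeric(amplitudePerLevel),
      excursionTimescale = as.numeric(excursionTimescale),
      jitterSd = as.numeric(jitterSd), dropoutRate = as.numeric(dropoutRate),
      nFrames = as.integer(nFrames), frameRate = as.numeric(frameRate),
      frameSize = as.integer(frameSize))
}

# fold values back into [lo, hi] by reflection at the borders
.reflectInto <- function(v, lo, hi) {
  while (any(v < lo | v > hi)) {
    v <- ifelse(v < lo, 2 * lo - v, v)
    v <- ifelse(v > hi, 2 * hi - v, v)
  }
  v
}

# slow drift: smoothed Gaussian random walk rescaled to a target RMS.
# Always consumes n normal draws so RNG streams stay aligned across levels.
.slowExcursion <- function(n, targetRms, timescale, frameRate) {
  w <- cumsum(stats::rnorm(n))
  if (targetRms <= 0) return(numeric(n))
  k <- min(n, max(1L, as.integer(round(timescale * frameRate))))
  sm <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 2, circular = TRUE))
  sm <- sm - mean(sm)
  r <- sqrt(mean(sm^2))
  if (r == 0) numeric(n) else sm * targetRms / r
}

#' Simulate one stick-figure pose sequence
#'
#' Distal landmarks (wrist/elbow when sitting, ankle/knee when lying) drift
#' slowly around the base posture with per-coordinate RMS
#' `level * amplitudePerLevel / sqrt(2)` pixels (so the 2D excursion RMS is
#' `level * amplitudePerLevel`); proximal landmarks stay at the base posture
#' up to jitter. Every point receives white pixel jitter; a `dropoutRate`
#' fraction is assigned a likelihood drawn in \[0, 0.8) (the rest in
#' \[0.8, 1\]) so the likelihood-cutoff path is exercised. Coordinates are
#' reflected back at the frame borders. Deterministic given `seed`.
#'
#' @param spec a [SyntheticSpec-class].
#' @param levelLeft,levelRight severity levels 0..4 for the two body sides.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param videoId,subjectId identifiers for the generated sequence.
#' @return A [PoseSequence-class].
#' @export
simulatePoseSequence <- function(spec, levelLeft, levelRight, seed = NULL,
                                 videoId = "sim_video",
                                 subjectId = "sim_subject") {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  for (lv in c(levelLeft, levelRight))
    if (!is.finite(lv) || lv != round(lv) || lv < 0 || lv > 4)
      stopf("severity levels must be integers in 0..4")
  gen <- function() {
    n <- spec@nFrames
    parts <- bodyPartNames()
    moving <- if (spec@position == "sitting") c("wrist", "elbow")
              else c("ankle", "knee")
    x <- matrix(NA_real_, n, 12L, dimnames = list(NULL, parts))
    y <- x; p <- x
    for (part in parts) {
      side <- .partSide(part); seg <- .partSegment(part)
      lvl <- if (side == "left") levelLeft else levelRight
      rms <- if (seg %in% moving)
               lvl * spec@amplitudePerLevel / sqrt(2) else 0
      base <- spec@basePosture[part, ]
      ex <- .slowExcursion(n, rms, spec@excursionTimescale, spec@frameRate)
      ey <- .slowExcursion(n, rms, spec@excursionTimescale, spec@frameRate)
      jx <- stats::rnorm(n, 0, spec@jitterSd)
      jy <- stats::rnorm(n, 0, spec@jitterSd)
      x[, part] <- .reflectInto(base[1] + ex + jx, 0, spec@frameSize[1])
      y[, part] <- .reflectInto(base[2] + ey + jy, 0, spec@frameSize[2])
      drop <- stats::runif(n) < spec@dropoutRate
      u <- stats::runif(n)
      p[, part] <- ifelse(drop, 0.8 * u, 0.8 + 0.2 * u)
    }
    PoseSequence(x, y, likelihood = p, videoId = videoId,
                 subjectId = subjectId, position = spec@position,
                 frameRate = spec@frameRate, frameSize = spec@frameSize)
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Generate a synthetic cohort with ground-truth scores
#'
#' Each subject draws one latent severity level per body side (uniform over
#' 0..4 by default) which is held constant across that subject's videos, as a
#' stable impairment would be; every video is simulated at those levels and
#' paired with a ground-truth score row per side for the position's item
#' (leg amplitude for lying, arm amplitude for sitting).
#'
#' @param nSubjects,videosPerSubject cohort dimensions.
#' @param spec a [SyntheticSpec-class].
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @param levelProbs probabilities of levels 0..4 (default uniform).
#' @return List with `sequences` (named list of [PoseSequence-class]),
#'   `scores` (ground-truth score table, rater `"truth"`) and `levels`
#'   (per-subject latent levels).
#' @export
generateCohort <- function(nSubjects, videosPerSubject, spec = syntheticSpec(),
                           seed = 42L, levelProbs = rep(0.2, 5)) {
  stopifnot(nSubjects >= 1L, videosPerSubject >= 1L, is(spec, "SyntheticSpec"))
  item <- if (spec@position == "sitting") "arm_amplitude" else "leg_amplitude"
  withr::with_seed(as.integer(seed), {
    subjects <- sprintf("S%02d", seq_len(nSubjects))
    lvlL <- sample(0:4, nSubjects, replace = TRUE, prob = levelProbs)
    lvlR <- sample(0:4, nSubjects, replace = TRUE, prob = levelProbs)
    seqs <- list(); scoreRows <- list()
    for (i in seq_len(nSubjects)) {
      for (v in seq_len(videosPerSubject)) {
        vid <- sprintf("%s_V%d", subjects[i], v)
        seqs[[vid]] <- simulatePoseSequence(spec, lvlL[i], lvlR[i],
                                            videoId = vid,
                                            subjectId = subjects[i])
        scoreRows[[vid]] <- data.frame(
          video_id = vid, rater_id = "truth", item = item,
          side = c("left", "right"), raw = c(lvlL[i], lvlR[i]),
          stringsAsFactors = FALSE)
      }
    }
    list(sequences = seqs,
         scores = do.call(rbind, c(scoreRows, list(make.row.names = FALSE))),
         levels = data.frame(subject_id = subjects, level_left = lvlL,
                             level_right = lvlR, stringsAsFactors = FALSE))
  })
}

#' Simulate an imperfect human rater
#'
#' Perturbs each raw score of a ground-truth table with rounded Gaussian
#' noise, clamped to 0..4. The expected disagreement with the truth (and
#' between two such raters) grows monotonically with `confusionSd`;
#' `confusionSd = 0` reproduces the input exactly.
#'
#' @param truth a score table.
#' @param confusionSd SD of the perturbation in raw score units.
#' @param seed integer seed.
#' @param raterId rater id of the perturbed table.
#' @return A score table with the same keys and perturbed raw scores.
#' @export
simulateRater <- function(truth, confusionSd, seed = 42L,
                          raterId = "sim_rater") {
  .validateScoreTable(truth)
  if (confusionSd < 0) stopf("confusionSd must be non-negative")
  out <- truth
  out$rater_id <- raterId
  out$raw <- withr::with_seed(as.integer(seed), {
    as.integer(pmin(4, pmax(0, round(truth$raw +
      stats::rnorm(nrow(truth), 0, confusionSd)))))
  })
  out
}
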