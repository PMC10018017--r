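# In-code fixtures: tiny pose sequences and geometric transforms.

# deterministic pose with distinct, non-degenerate landmark positions
makePose <- function(n = 10, position = "lying", videoId = "v",
                     subjectId = "s", x = NULL, y = NULL, likelihood = NULL) {
  parts <- bodyPartNames()
  baseX <- matrix(rep(seq(100, 650, length.out = 12), each = n), n, 12,
                  dimnames = list(NULL, parts))
  baseY <- matrix(rep(seq(80, 520, length.out = 12), each = n), n, 12,
                  dimnames = list(NULL, parts))
  PoseSequence(x = if (is.null(x)) baseX else x,
               y = if (is.null(y)) baseY else y,
               likelihood = likelihood, videoId = videoId,
               subjectId = subjectId, position = position)
}

# smooth random motion around distinct base positions, no masked points
randomPose <- function(n = 50, seed = 1, position = "lying") {
  withr::with_seed(seed, {
    parts <- bodyPartNames()
    x <- matrix(NA_real_, n, 12, dimnames = list(NULL, parts))
    y <- x
    bx <- seq(120, 620, length.out = 12)
    by <- seq(100, 500, length.out = 12) * c(1, 1.07)  # break collinearity
    for (k in 1:12) {
      x[, k] <- bx[k] + cumsum(rnorm(n, 0, 2))
      y[, k] <- by[k] + cumsum(rnorm(n, 0, 2))
    }
    PoseSequence(x, y, videoId = "rnd", subjectId = "rnd",
                 position = position)
  })
}

# rigid transform (+ optional reflection) applied uniformly to every frame
applyIsometry <- function(seq, theta = 0, tx = 0, ty = 0, mirror = FALSE) {
  x <- coordX(seq); y <- coordY(seq)
  if (mirror) x <- -x
  xr <- cos(theta) * x - sin(theta) * y + tx
  yr <- sin(theta) * x + cos(theta) * y + ty
  PoseSequence(xr, yr, likelihood = likelihoods(seq),
               missing = missingMask(seq), videoId = videoId(seq),
               subjectId = subjectId(seq), position = posePosition(seq))
}

# sample table with an exact monotone feature-target relation plus noise cols
separableSamples <- function(nSubjects = 50, perSubject = 2, seed = 7) {
  withr::with_seed(seed, {
    n <- nSubjects * perSubject
    target <- sample(c(0, 0.25, 0.5, 0.75, 1), n, replace = TRUE)
    data.frame(subject_id = rep(sprintf("P%03d", seq_len(nSubjects)),
                                each = perSubject),
               video_id = sprintf("v%03d", seq_len(n)),
               position = "lying",
               side = rep(c("left", "right"), length.out = n),
               f_signal = 100 * target,
               f_noise1 = rnorm(n), f_noise2 = rnorm(n), f_noise3 = rnorm(n),
               target = target, stringsAsFactors = FALSE)
  })
}
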