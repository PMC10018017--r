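# Geometric posture features and windowed-median reduction.

test_that("distance-to-middle-point matches hand-worked cases", {
  expect_equal(distanceToMiddlePoint(cbind(c(5, 5, 5), c(2, 2, 2))),
               c(0, 0, 0))
  expect_equal(distanceToMiddlePoint(cbind(c(0, 2), c(0, 0))), c(1, 1))
  expect_equal(distanceToMiddlePoint(cbind(c(0, 0, 0), c(0, 4, 8))),
               c(4, 0, 4))
  expect_error(distanceToMiddlePoint(cbind(c(0, NA), c(0, 1))), "missing")
})

test_that("distance-to-middle-point is zero everywhere iff the track is constant", {
  set.seed(2)
  for (i in 1:20) {
    trk <- cbind(cumsum(rnorm(30)), cumsum(rnorm(30)))
    d <- distanceToMiddlePoint(trk)
    expect_identical(all(d < 1e-12),
                     all(abs(diff(trk[, 1])) < 1e-12) &&
                     all(abs(diff(trk[, 2])) < 1e-12))
  }
})

test_that("distance-to-line matches closed-form cases and rejects degeneracy", {
  expect_equal(distanceToLine(c(3, 5), c(0, 0), c(0, 10)), 3)
  expect_equal(distanceToLine(c(0, 7), c(0, 0), c(0, 10)), 0)
  expect_equal(distanceToLine(c(10, 0), c(0, 0), c(10, 10)), 5 * sqrt(2),
               tolerance = 1e-9)  # 7.0711
  expect_error(distanceToLine(c(1, 1), c(2, 2), c(2, 2)), "degenerate")
})

test_that("distance-to-line agrees with brute-force search along the line", {
  # oracle: coarse scan over points on the line, then golden-section refine
  bruteDist <- function(p, a, b) {
    f <- function(t) sqrt(sum((a + t * (b - a) - p)^2))
    ts <- seq(-10, 11, length.out = 20001)
    i <- which.min(vapply(ts, f, 0))
    lo <- ts[max(1, i - 1)]; hi <- ts[min(length(ts), i + 1)]
    stats::optimize(f, c(lo, hi), tol = 1e-12)$objective
  }
  set.seed(13)
  for (i in 1:100) {
    p <- runif(2, 0, 100); a <- runif(2, 0, 100); b <- runif(2, 0, 100)
    if (sum((a - b)^2) < 1e-6) next
    expect_equal(distanceToLine(p, a, b), bruteDist(p, a, b),
                 tolerance = 1e-6)
  }
})

test_that("joint angle reproduces closed-form cases in degrees", {
  expect_equal(jointAngle(c(0, 0), c(0, 1), c(1, 1)), 90)
  expect_equal(jointAngle(c(-1, 0), c(0, 0), c(1, 0)), 180)  # straight limb
  expect_equal(jointAngle(c(1, 0), c(0, 0), c(0.5, 0.8660254)), 60,
               tolerance = 1e-6)
  expect_error(jointAngle(c(0, 0), c(0, 0), c(1, 1)), "zero-length")
})

test_that("windowed median reduces blocks as specified", {
  expect_equal(windowedMedian(rep(5, 500), 10), rep(5, 10))
  # frozen: median of each contiguous 50-block of 0..499
  expect_equal(windowedMedian(0:499, 10),
               c(24.5, 74.5, 124.5, 174.5, 224.5, 274.5, 324.5, 374.5,
                 424.5, 474.5))
  expect_error(windowedMedian(1:10, 3), "divisible")
})

test_that("windowed median shifts with an added constant", {
  set.seed(3)
  tr <- rnorm(200)
  expect_equal(windowedMedian(tr + 7, 10), windowedMedian(tr, 10) + 7)
})

test_that("a preprocessed sequence yields 60 ordered feature values", {
  cfg <- ScoringConfig()
  ps <- preprocessPose(simulatePoseSequence(syntheticSpec("lying"), 2, 1,
                                            seed = 8), cfg)
  for (side in c("left", "right")) {
    fv <- buildSampleFeatures(ps, side, cfg)
    expect_length(fv, 60)
    expect_true(all(is.finite(fv)))
    expect_true(all(fv[1:50] >= 0))                  # distances
    expect_true(all(fv[51:60] >= 0 & fv[51:60] <= 180))  # angles
    expect_identical(names(fv)[1:2], c("d2m_ankle_w01", "d2m_ankle_w02"))
    expect_identical(names(fv)[60], "angle_knee_w10")
  }
  # sitting plan uses the arm landmarks
  pss <- preprocessPose(simulatePoseSequence(syntheticSpec("sitting"), 2, 1,
                                             seed = 8), cfg)
  fvs <- buildSampleFeatures(pss, "left", cfg)
  expect_identical(names(fvs)[1], "d2m_wrist_w01")
  expect_identical(names(fvs)[60], "angle_elbow_w10")
  expect_error(buildSampleFeatures(simulatePoseSequence(
    syntheticSpec("lying", nFrames = 100), 0, 0, seed = 1), "left", cfg),
    "preprocessPose")
})

test_that("a perfectly static lying posture has all-zero d2m features", {
  spec <- syntheticSpec("lying", jitterSd = 0, dropoutRate = 0)
  ps <- simulatePoseSequence(spec, 0, 0, seed = 1)
  fv <- buildSampleFeatures(ps, "left", ScoringConfig())
  expect_equal(unname(fv[1:30]), rep(0, 30))
})

test_that("features are invariant under rigid transforms and reflection", {
  cfg <- ScoringConfig(targetLength = 60L, nWindows = 10L)
  set.seed(21)
  for (i in 1:5) {
    ps <- randomPose(60, seed = 30 + i)
    ref <- buildSampleFeatures(ps, "left", cfg)
    tr <- applyIsometry(ps, theta = runif(1, 0, 2 * pi),
                        tx = runif(1, -200, 200), ty = runif(1, -200, 200),
                        mirror = i %% 2 == 0)
    expect_equal(buildSampleFeatures(tr, "left", cfg), ref,
                 tolerance = 1e-9)
  }
})

test_that("mirroring x about the frame preserves the feature vector", {
  cfg <- ScoringConfig(targetLength = 60L, nWindows = 10L)
  ps <- randomPose(60, seed = 44)
  mir <- PoseSequence(720 - coordX(ps), coordY(ps), videoId = "m",
                      subjectId = "m", position = posePosition(ps))
  expect_equal(buildSampleFeatures(mir, "left", cfg),
               buildSampleFeatures(ps, "left", cfg), tolerance = 1e-9)
})

test_that("feature extraction is deterministic on identical input", {
  cfg <- ScoringConfig(targetLength = 60L, nWindows = 10L)
  ps <- randomPose(60, seed = 5)
  expect_identical(buildSampleFeatures(ps, "right", cfg),
                   buildSampleFeatures(ps, "right", cfg))
})

test_that("side split yields two keyed samples per video", {
  cfg <- ScoringConfig()
  ps <- preprocessPose(simulatePoseSequence(syntheticSpec("lying"), 1, 3,
                                            seed = 2, videoId = "vid7",
                                            subjectId = "subj3"), cfg)
  tab <- splitSides(ps, cfg)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$side, c("left", "right"))
  expect_equal(unique(tab$video_id), "vid7")
  expect_equal(unique(tab$subject_id), "subj3")
  expect_length(dyskscore:::featureColumns(tab), 60)
})

test_that("a mirror-symmetric skeleton gives equal left and right samples", {
  n <- 60
  cfg <- ScoringConfig(targetLength = as.integer(n), nWindows = 10L)
  withr::with_seed(10, {
    parts <- bodyPartNames()
    x <- matrix(NA_real_, n, 12, dimnames = list(NULL, parts))
    y <- x
    for (seg in dyskscore:::.bodySegments) {
      lx <- 360 + seq(10, 60, length.out = 6)[match(seg,
              dyskscore:::.bodySegments)] + cumsum(rnorm(n))
      ly <- 100 + 60 * match(seg, dyskscore:::.bodySegments) + cumsum(rnorm(n))
      x[, paste0("left_", seg)] <- lx
      x[, paste0("right_", seg)] <- 720 - lx   # exact mirror twin
      y[, paste0("left_", seg)] <- ly
      y[, paste0("right_", seg)] <- ly
    }
    ps <- PoseSequence(x, y, videoId = "sym", subjectId = "sym",
                       position = "sitting")
    tab <- splitSides(ps, cfg)
    f <- dyskscore:::featureColumns(tab)
    expect_equal(unlist(tab[1, f]), unlist(tab[2, f]), tolerance = 1e-9)
  })
})

test_that("a degenerate bodyline error names the failing side", {
  n <- 60
  cfg <- ScoringConfig(targetLength = as.integer(n), nWindows = 10L)
  ps <- randomPose(n, seed = 3)
  x <- coordX(ps); y <- coordY(ps)
  x[, "left_shoulder"] <- x[, "left_hip"]
  y[, "left_shoulder"] <- y[, "left_hip"]
  bad <- PoseSequence(x, y, videoId = "v", subjectId = "s", position = "lying")
  expect_error(splitSides(bad, cfg), "side 'left'.*degenerate")
})

test_that("feature export writes coded columns with a dictionary", {
  cfg <- ScoringConfig()
  ps <- preprocessPose(simulatePoseSequence(syntheticSpec("sitting"), 1, 1,
                                            seed = 6), cfg)
  tab <- splitSides(ps, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, path)
  back <- read.csv(path)
  expect_true(all(sprintf("f%02d", 0:59) %in% names(back)))
  dict <- yaml::read_yaml(paste0(path, ".dict.yaml"))
  expect_identical(dict$f00, "d2m_wrist_w01")
  expect_identical(dict$f59, "angle_elbow_w10")
})
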