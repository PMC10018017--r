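# Keypoint table I/O and preprocessing.

test_that("write/read round-trips coordinates, likelihoods and masks exactly", {
  set.seed(11)
  n <- 20L
  lik <- matrix(runif(n * 12), n, 12, dimnames = list(NULL, bodyPartNames()))
  ps <- makePose(n, likelihood = lik)
  # mask a few points to exercise empty-cell serialization
  miss <- missingMask(ps)
  miss[c(1, 7, 13), c(2, 5)] <- TRUE
  ps <- dyskscore:::.replaceAssays(ps, missing = miss)

  path <- withr::local_tempfile(fileext = ".csv")
  writePoseTable(ps, path)
  back <- readPoseTable(path, videoId(ps), subjectId(ps), posePosition(ps))

  expect_identical(nFrames(back), n)
  keep <- !missingMask(ps)
  expect_identical(coordX(back)[keep], coordX(ps)[keep])
  expect_identical(coordY(back)[keep], coordY(ps)[keep])
  expect_identical(likelihoods(back), likelihoods(ps))
  expect_identical(missingMask(back), missingMask(ps))
})

test_that("a well-formed 500-frame table yields 500 frames and 12 landmarks", {
  ps <- makePose(500)
  path <- withr::local_tempfile(fileext = ".csv")
  writePoseTable(ps, path)
  back <- readPoseTable(path, "v", "s", "lying")
  expect_equal(nFrames(back), 500)
  expect_setequal(rownames(back), bodyPartNames())
})

test_that("malformed tables are rejected with informative errors", {
  ps <- makePose(5)
  path <- withr::local_tempfile(fileext = ".csv")
  writePoseTable(ps, path)
  lines <- readLines(path)

  # drop the left_wrist columns entirely
  drop <- which(strsplit(lines[2], ",")[[1]] == "left_wrist")
  mut <- vapply(lines, function(l)
    paste(strsplit(l, ",")[[1]][-drop], collapse = ","), "")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(mut, p2)
  expect_error(readPoseTable(p2, "v", "s", "lying"), "left_wrist")

  # corrupt one cell: error names row and column
  cells <- strsplit(lines[5], ",")[[1]]
  cells[3] <- "oops"
  lines2 <- lines; lines2[5] <- paste(cells, collapse = ",")
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines2, p3)
  expect_error(readPoseTable(p3, "v", "s", "lying"), "oops.*row 2.*left_wrist_y")

  expect_error(readPoseTable(withr::local_tempfile(), "v", "s", "lying"),
               "does not exist")
})

test_that("unknown bodypart columns are ignored with a warning", {
  ps <- makePose(4)
  path <- withr::local_tempfile(fileext = ".csv")
  writePoseTable(ps, path)
  lines <- readLines(path)
  lines[1] <- paste0(lines[1], ",dyskscore,dyskscore,dyskscore")
  lines[2] <- paste0(lines[2], ",nose,nose,nose")
  lines[3] <- paste0(lines[3], ",x,y,likelihood")
  lines[4:7] <- paste0(lines[4:7], ",1,2,0.5")
  writeLines(lines, path)
  expect_warning(back <- readPoseTable(path, "v", "s", "lying"), "nose")
  expect_equal(nFrames(back), 4)
  expect_setequal(rownames(back), bodyPartNames())
})

test_that("flat single-header dialect is accepted", {
  tab <- data.frame(frame = 0:2)
  for (p in bodyPartNames()) {
    tab[[paste0(p, "_x")]] <- c(1, 2, 3)
    tab[[paste0(p, "_y")]] <- c(4, 5, 6)
    tab[[paste0(p, "_p")]] <- 0.9
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- readPoseTable(path, "v", "s", "sitting")
  expect_equal(nFrames(back), 3)
  expect_equal(unname(coordX(back)[, "left_knee"]), c(1, 2, 3))
  expect_equal(unname(likelihoods(back)[2, "right_hip"]), 0.9)
})

test_that("a PoseSequence cannot be empty", {
  expect_error(makePose(0), "at least one frame")
})

test_that("likelihood cutoff masks strictly-below points and nothing else", {
  lik <- matrix(1, 3, 12, dimnames = list(NULL, bodyPartNames()))
  lik[1, 1] <- 0.79; lik[2, 1] <- 0.80; lik[3, 1] <- 0.81
  ps <- makePose(3, likelihood = lik)
  cut <- applyLikelihoodCutoff(ps, 0.8)
  expect_true(missingMask(cut)[1, 1])    # p = 0.79 masked
  expect_false(missingMask(cut)[2, 1])   # boundary p = 0.80 retained
  expect_false(missingMask(cut)[3, 1])
  expect_identical(coordX(cut), coordX(ps))  # coordinates never altered
  expect_identical(coordY(cut), coordY(ps))

  expect_identical(missingMask(applyLikelihoodCutoff(ps, 0)),
                   missingMask(ps))          # cutoff 0 is the identity
  expect_error(applyLikelihoodCutoff(ps, 1.2), "\\[0, 1\\]")
})

test_that("cutoff is idempotent and monotone in the threshold", {
  set.seed(4)
  lik <- matrix(runif(40 * 12), 40, 12, dimnames = list(NULL, bodyPartNames()))
  ps <- makePose(40, likelihood = lik)
  once <- applyLikelihoodCutoff(ps, 0.5)
  twice <- applyLikelihoodCutoff(once, 0.5)
  expect_identical(missingMask(once), missingMask(twice))
  for (cuts in list(c(0.2, 0.5), c(0.5, 0.9))) {
    lo <- missingMask(applyLikelihoodCutoff(ps, cuts[1]))
    hi <- missingMask(applyLikelihoodCutoff(ps, cuts[2]))
    expect_true(all(hi[lo]))  # raising the cutoff never unmasks a point
  }
})

test_that("gap interpolation fills interior gaps linearly and holds edges", {
  ps <- makePose(3)
  x <- coordX(ps); x[, "left_knee"] <- c(0, NA, 10)
  y <- coordY(ps); y[, "left_knee"] <- c(0, NA, 10)
  ps2 <- makePose(3, x = x, y = y)
  out <- interpolateGaps(ps2)
  expect_equal(unname(coordX(out)[, "left_knee"]), c(0, 5, 10))
  expect_false(any(missingMask(out)))

  x[, "left_knee"] <- c(NA, 4, 4); y[, "left_knee"] <- c(NA, 4, 4)
  out2 <- interpolateGaps(makePose(3, x = x, y = y))
  expect_equal(unname(coordX(out2)[, "left_knee"]), c(4, 4, 4))

  x[, "left_knee"] <- NA_real_
  expect_error(interpolateGaps(makePose(3, x = x, y = y)), "left_knee")
})

test_that("interpolation leaves observed points bit-unchanged", {
  set.seed(9)
  ps <- randomPose(60)
  miss <- missingMask(ps)
  miss[sample(length(miss), 100)] <- TRUE
  miss[c(1, 60), ] <- FALSE  # keep >= 2 observed per landmark
  ps2 <- dyskscore:::.replaceAssays(ps, missing = miss)
  out <- interpolateGaps(ps2)
  keep <- !miss
  expect_identical(coordX(out)[keep], coordX(ps)[keep])
  expect_identical(coordY(out)[keep], coordY(ps)[keep])
})

test_that("cyclic extrapolation tiles whole frames in order", {
  ps <- randomPose(100)
  out <- extrapolateToLength(ps, 500)
  expect_equal(nFrames(out), 500)
  expect_identical(coordX(out)[101, ], coordX(ps)[1, ])  # frame 100 = frame 0
  expect_identical(coordX(out)[500, ], coordX(ps)[100, ])

  expect_identical(extrapolateToLength(ps, 100), ps)     # identity at target

  ps475 <- randomPose(475)
  out475 <- extrapolateToLength(ps475, 500)
  expect_identical(coordX(out475)[476:500, ], coordX(ps475)[1:25, ])
  expect_identical(coordY(out475)[476:500, ], coordY(ps475)[1:25, ])

  expect_error(extrapolateToLength(randomPose(501), 500), "truncate")
})

test_that("tiling preserves the mean position at integer multiples", {
  ps <- randomPose(100)
  out <- extrapolateToLength(ps, 500)
  expect_equal(colMeans(coordX(out)), colMeans(coordX(ps)), tolerance = 1e-12)
  expect_equal(colMeans(coordY(out)), colMeans(coordY(ps)), tolerance = 1e-12)
})

test_that("preprocessPose yields a complete sequence at the target length", {
  spec <- syntheticSpec("lying", nFrames = 230, dropoutRate = 0.05)
  ps <- simulatePoseSequence(spec, 2, 3, seed = 5)
  out <- preprocessPose(ps, ScoringConfig())
  expect_equal(nFrames(out), 500)
  expect_false(any(missingMask(out)))
})
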