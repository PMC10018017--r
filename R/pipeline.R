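# End-to-end orchestration: pose tables + score table -> per-rater reports.

#' Serialize a ModelReport
#'
#' Plain-list view of a [ModelReport-class] suitable for JSON export; the
#' report JSON itself contains no timestamps so reruns on identical inputs
#' are byte-identical.
#'
#' @param report a [ModelReport-class].
#' @param config the [ScoringConfig-class] used (echoed into the output).
#' @return A named list.
#' @export
reportAsList <- function(report, config = NULL) {
  out <- list(
    rater_id = report@raterId, item = report@item,
    mae = report@mae, sd = report@sd, n = report@n,
    fold_sizes = report@foldSizes, seed = report@seed,
    confusion = unname(apply(report@confusion, 1L, as.integer,
                             simplify = FALSE)),
    confusion_levels = .disLevels,
    predictions = predictions(report))
  if (!is.null(config))
    out$config <- list(p_cutoff = config@pCutoff,
                       target_length = config@targetLength,
                       n_windows = config@nWindows, n_folds = config@nFolds,
                       n_trees = config@nTrees, seed = config@seed)
  out
}

#' Run the full scoring pipeline
#'
#' Ingests every keypoint table listed in the metadata table, preprocesses it
#' (likelihood cutoff, interpolation, extrapolation), computes per-side
#' feature vectors, joins the clinical scores and trains/evaluates one
#' grouped-CV random forest per (rater, item). Videos present only in the
#' metadata or only in the score table are skipped with a warning, never
#' imputed; skip counts are surfaced in the manifest. Identical inputs and
#' config yield byte-identical report JSON.
#'
#' @param poseDir directory of keypoint CSVs.
#' @param metaPath CSV with columns `video_id, subject_id, position` and
#'   optionally `file` (default `<video_id>.csv` inside `poseDir`).
#' @param scoresPath DIS score CSV.
#' @param outDir output directory; created if needed. Reports are written as
#'   `report_<rater>_<item>.json` plus `manifest.json` and `features.csv`.
#' @param config a [ScoringConfig-class].
#' @return Named list of [ModelReport-class] objects, invisibly.
#' @export
runPipeline <- function(poseDir, metaPath, scoresPath, outDir,
                        config = ScoringConfig()) {
  t0 <- Sys.time()
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE,
                          colClasses = c(video_id = "character",
                                         subject_id = "character"))
  need <- c("video_id", "subject_id", "position")
  if (!all(need %in% names(meta)))
    stopf("metadata table needs columns %s", paste(need, collapse = ", "))
  scores <- readScoreTable(scoresPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  files <- if ("file" %in% names(meta)) meta$file
           else paste0(meta$video_id, ".csv")
  paths <- file.path(poseDir, files)
  scored <- meta$video_id %in% scores$video_id
  readable <- file.exists(paths)
  skippedNoScore <- sum(!scored)
  skippedNoPose <- sum(scored & !readable)
  if (skippedNoScore)
    warnf("%d video(s) without scores skipped", skippedNoScore)
  if (skippedNoPose)
    warnf("%d scored video(s) without a pose table skipped", skippedNoPose)
  use <- which(scored & readable)
  if (!length(use)) stopf("stage ingest: no usable videos")

  message(sprintf("[ingest] reading %d pose tables", length(use)))
  seqs <- lapply(use, function(i)
    tryCatch(readPoseTable(paths[i], meta$video_id[i], meta$subject_id[i],
                           meta$position[i]),
             error = function(e) stopf("stage ingest, video '%s': %s",
                                       meta$video_id[i],
                                       conditionMessage(e))))
  message("[features] preprocessing and extracting feature vectors")
  feats <- tryCatch(featureTable(seqs, config),
                    error = function(e) stopf("stage features: %s",
                                              conditionMessage(e)))
  writeFeatureTable(feats, file.path(outDir, "features.csv"))

  message("[train] grouped cross-validation per rater and item")
  reports <- trainPerRater(feats, scores, config)
  for (r in reports) assertNoLeakage(r)
  for (nm in names(reports)) {
    fn <- file.path(outDir, sprintf("report_%s.json", gsub(":", "_", nm)))
    jsonlite::write_json(reportAsList(reports[[nm]], config), fn,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  manifest <- list(
    package = "dyskscore",
    version = as.character(utils::packageVersion("dyskscore")),
    seed = config@seed,
    config = reportAsList(new("ModelReport", raterId = "", item = "",
                              predictions = data.frame(), mae = 0, sd = 0,
                              n = 0L, confusion = matrix(0L, 5, 5),
                              foldSizes = integer(config@nFolds),
                              seed = config@seed), config)$config,
    inputs = list(meta = unname(tools::md5sum(metaPath)),
                  scores = unname(tools::md5sum(scoresPath)),
                  pose_tables = as.list(tools::md5sum(paths[use]))),
    stages = list(ingest = list(n_videos = length(use),
                                skipped_no_score = skippedNoScore,
                                skipped_no_pose = skippedNoPose),
                  features = list(n_samples = nrow(feats)),
                  train = list(reports = names(reports))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(reports)
}

#' Write a synthetic cohort to disk in pipeline input format
#'
#' Emits one keypoint CSV per generated video plus `meta.csv` and
#' `scores.csv`, ready for [runPipeline()].
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    video_id = vapply(cohort$sequences, videoId, ""),
    subject_id = vapply(cohort$sequences, subjectId, ""),
    position = vapply(cohort$sequences, posePosition, ""),
    stringsAsFactors = FALSE)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  writeScoreTable(cohort$scores, file.path(dir, "scores.csv"))
  for (s in cohort$sequences)
    writePoseTable(s, file.path(dir, paste0(videoId(s), ".csv")))
  invisible(dir)
}
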