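# Random-forest regression of normalized DIS scores from feature vectors,
# evaluated by subject-grouped k-fold cross-validation.

#' Subject-grouped fold assignment
#'
#' Partitions samples into `k` folds such that all samples of one subject --
#' and therefore both side-samples of every video -- land in the same fold.
#' Subjects are assigned greedily in descending sample count to the currently
#' smallest fold, with a seeded shuffle breaking ties among subjects with
#' equal counts and among equally small folds, so the split is deterministic
#' given the seed while balancing fold sizes.
#'
#' @param subjectIds character vector, one subject id per sample.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold indices (1..k), one per sample.
#' @export
groupedFolds <- function(subjectIds, k = 5L, seed = 42L) {
  k <- as.integer(k)
  counts <- table(subjectIds)
  if (length(counts) < k)
    stopf("%d distinct subjects cannot fill %d folds", length(counts), k)
  foldOf <- withr::with_seed(seed, {
    counts <- counts[sample(length(counts))]          # shuffle ties
    counts <- counts[order(-as.integer(counts))]      # stable: keeps shuffle
    sizes <- integer(k)
    fo <- stats::setNames(integer(length(counts)), names(counts))
    for (i in seq_along(counts)) {
      cand <- which(sizes == min(sizes))
      pick <- if (length(cand) > 1L) sample(cand, 1L) else cand
      fo[i] <- pick
      sizes[pick] <- sizes[pick] + as.integer(counts[i])
    }
    fo
  })
  unname(foldOf[as.character(subjectIds)])
}

#' Train the random-forest score regressor
#'
#' Fits a seeded random-forest regression (squared-error splitting, trees
#' grown without a depth limit, `config@nTrees` trees) of the normalized
#' score on the feature columns. Constant training targets yield, with a
#' warning, a degenerate model that always predicts that constant. Because
#' forest predictions average training targets, predictions always lie within
#' the training target range.
#'
#' @param samples sample table: feature columns plus a `target` column of
#'   normalized scores (see [assembleSamples()]).
#' @param config a [ScoringConfig-class].
#' @param seed seed for the forest; defaults to `config@seed`.
#' @return An object of class `dysForest` with a `predict()` method.
#' @export
trainModel <- function(samples, config = ScoringConfig(), seed = config@seed) {
  fcols <- featureColumns(samples)
  if (nrow(samples) < 2L) stopf("need at least 2 training samples")
  y <- samples$target
  if (is.null(y)) stopf("samples must carry a 'target' column")
  if (length(unique(y)) < 2L) {
    warnf("constant training targets; model will predict %.3f", y[1])
    fit <- list(constant = y[1], features = fcols)
  } else {
    x <- as.matrix(samples[, fcols, drop = FALSE])
    # mtry = p: every split considers all features, matching the reference
    # regressor's default. Regression on the 5-level normalized scale is
    # deliberate; muffle the forest's few-unique-values advisory.
    rf <- withCallingHandlers(
      withr::with_seed(as.integer(seed),
        randomForest::randomForest(x = x, y = y, ntree = config@nTrees,
                                   mtry = ncol(x))),
      warning = function(w) {
        if (grepl("five or fewer unique values", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    fit <- list(forest = rf, features = fcols, range = range(y))
  }
  structure(fit, class = "dysForest")
}

#' @param object a `dysForest`.
#' @param newdata sample table or feature matrix.
#' @param ... unused.
#' @rdname trainModel
#' @export
predict.dysForest <- function(object, newdata, ...) {
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(newdata)))
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  as.numeric(stats::predict(object$forest, x))
}

#' Attach normalized score targets to a feature table
#'
#' Joins one rater's scores for one item onto the matching samples of a
#' feature table. The item fixes the rest position (arm amplitude is scored
#' on sitting videos, leg amplitude on lying videos); the join key is
#' (video_id, side). Feature-table rows without a score are dropped.
#'
#' @param features table from [featureTable()].
#' @param scores a DIS score table.
#' @param raterId rater whose scores to use.
#' @param item `"arm_amplitude"` or `"leg_amplitude"`.
#' @return Sample table: meta columns, feature columns and `target`.
#' @export
assembleSamples <- function(features, scores, raterId,
                            item = c("arm_amplitude", "leg_amplitude")) {
  item <- match.arg(item)
  .validateScoreTable(scores)
  pos <- if (item == "arm_amplitude") "sitting" else "lying"
  f <- features[features$position == pos, , drop = FALSE]
  s <- scores[scores$rater_id == raterId & scores$item == item, , drop = FALSE]
  m <- merge(f, s[, c("video_id", "side", "raw")], by = c("video_id", "side"))
  if (nrow(m) == 0L) return(m)
  m$target <- normalizeScore(m$raw)
  m$raw <- NULL
  m$rater_id <- as.character(raterId)
  m$item <- item
  m
}

#' Subject-grouped cross-validated evaluation
#'
#' Splits the samples with [groupedFolds()], trains one forest per fold on
#' the remaining folds (fold `f` uses seed `config@seed + f`), and predicts
#' each left-out fold, so every sample is predicted exactly once by a model
#' that never saw its subject. Absolute errors are pooled over all samples;
#' the report carries MAE, the sample SD of the absolute errors and the 5x5
#' confusion matrix of discretized predictions.
#'
#' @param samples sample table from [assembleSamples()] (needs `subject_id`
#'   and `target` plus feature columns).
#' @param config a [ScoringConfig-class].
#' @return A [ModelReport-class].
#' @export
crossValidate <- function(samples, config = ScoringConfig()) {
  k <- config@nFolds
  fold <- groupedFolds(samples$subject_id, k, config@seed)
  pred <- rep(NA_real_, nrow(samples))
  for (f in seq_len(k)) {
    test <- fold == f
    trainSub <- samples[!test, , drop = FALSE]
    # leakage guard: the held-out subjects must be absent from training
    leaked <- intersect(unique(samples$subject_id[test]),
                        unique(trainSub$subject_id))
    if (length(leaked))
      stopf("fold leakage for subject(s) %s", paste(leaked, collapse = ", "))
    model <- trainModel(trainSub, config, seed = config@seed + f)
    pred[test] <- predict(model, samples[test, , drop = FALSE])
  }
  stopifnot(!anyNA(pred))
  s <- .absErrorSummary(samples$target, pred)
  preds <- data.frame(subject_id = samples$subject_id,
                      video_id = samples$video_id, side = samples$side,
                      fold = fold, target = samples$target, prediction = pred,
                      abs_error = abs(samples$target - pred),
                      stringsAsFactors = FALSE)
  new("ModelReport",
      raterId = if (!is.null(samples$rater_id))
                  as.character(samples$rater_id[1]) else NA_character_,
      item = if (!is.null(samples$item)) samples$item[1] else NA_character_,
      predictions = preds, mae = s$mae, sd = s$sd, n = as.integer(s$n),
      confusion = confusionMatrix5(samples$target, pred),
      foldSizes = as.integer(tabulate(fold, nbins = k)),
      seed = config@seed)
}

#' Train and evaluate one model per (rater, item)
#'
#' Raters disagree, so a separate regressor is trained and evaluated against
#' each rater's own scores, for arm and leg amplitude independently.
#' Rater-item combinations with no matched samples are skipped with a
#' warning.
#'
#' @param features table from [featureTable()].
#' @param scores score table possibly holding several raters.
#' @param config a [ScoringConfig-class].
#' @return Named list of [ModelReport-class] objects
#'   (`"<rater>:<item>"`).
#' @export
trainPerRater <- function(features, scores, config = ScoringConfig()) {
  .validateScoreTable(scores)
  out <- list()
  for (r in unique(scores$rater_id)) {
    for (it in .scoreItems) {
      samples <- assembleSamples(features, scores, r, it)
      if (nrow(samples) == 0L) {
        warnf("no matched samples for rater %s, item %s; skipped", r, it)
        next
      }
      out[[paste(r, it, sep = ":")]] <- crossValidate(samples, config)
    }
  }
  out
}

#' Verify the no-leakage invariant of a report
#'
#' Checks programmatically that no subject's samples are split across folds
#' in the pooled predictions.
#'
#' @param report a [ModelReport-class].
#' @return `TRUE` (invisibly) or an error.
#' @export
assertNoLeakage <- function(report) {
  p <- predictions(report)
  byFold <- tapply(p$fold, p$subject_id, function(f) length(unique(f)))
  if (any(byFold > 1L))
    stopf("subject(s) %s span multiple folds",
          paste(names(byFold)[byFold > 1L], collapse = ", "))
  invisible(TRUE)
}
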