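#' Accessors for evaluation report objects
#'
#' Shared accessors for [AgreementReport-class], [ModelReport-class] and
#' [TrackingEval-class]: `mae()` returns the mean absolute error (normalized
#' score units for agreement/model reports, pixels for tracking), `maeSD()` the
#' sample standard deviation of the absolute errors, `nSamples()` the number of
#' evaluated pairs, `confusion()` the 5x5 level confusion matrix and
#' `predictions()` the per-sample prediction table of a `ModelReport`.
#'
#' @param x a report object.
#' @name report-accessors
#' @aliases mae maeSD nSamples confusion predictions
NULL

#' @rdname report-accessors
#' @export
setMethod("mae", "AgreementReport", function(x) x@mae)
#' @rdname report-accessors
#' @export
setMethod("maeSD", "AgreementReport", function(x) x@sd)
#' @rdname report-accessors
#' @export
setMethod("nSamples", "AgreementReport", function(x) x@n)
#' @rdname report-accessors
#' @export
setMethod("confusion", "AgreementReport", function(x) x@confusion)

#' @rdname report-accessors
#' @export
setMethod("mae", "ModelReport", function(x) x@mae)
#' @rdname report-accessors
#' @export
setMethod("maeSD", "ModelReport", function(x) x@sd)
#' @rdname report-accessors
#' @export
setMethod("nSamples", "ModelReport", function(x) x@n)
#' @rdname report-accessors
#' @export
setMethod("confusion", "ModelReport", function(x) x@confusion)
#' @rdname report-accessors
#' @export
setMethod("predictions", "ModelReport", function(x) x@predictions)

#' @rdname report-accessors
#' @export
setMethod("mae", "TrackingEval", function(x) x@mae)
#' @rdname report-accessors
#' @export
setMethod("nSamples", "TrackingEval", function(x) x@nUsed)

#' @export
setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (%s)\n", object@item),
      sprintf("  MAE %.3f +/- %.3f over %d overlapping samples\n",
              object@mae, object@sd, object@n), sep = "")
})

#' @export
setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport: rater %s, %s\n", object@raterId, object@item),
      sprintf("  pooled out-of-fold MAE %.3f +/- %.3f (n = %d)\n",
              object@mae, object@sd, object@n),
      sprintf("  folds: %s | seed %d\n",
              paste(object@foldSizes, collapse = "/"), object@seed), sep = "")
})

#' @export
setMethod("show", "TrackingEval", function(object) {
  cut <- if (is.na(object@pCutoff)) "no p-cutoff"
         else sprintf("p-cutoff %.2f", object@pCutoff)
  cat(sprintf("TrackingEval (%s)\n", cut),
      sprintf("  MAE %.2f px over %d points (%d excluded)\n",
              object@mae, object@nUsed, object@nExcluded), sep = "")
})
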