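#' @export
setMethod("show", "KFactorSpec", function(object) {
  cat(sprintf("k-factor (%s): %.4f [%s", object@purpose, object@value,
              object@distribution))
  if (length(object@nBlanks))
    cat(", N_b =", object@nBlanks)
  if (object@purpose == "LOD" && !anyNA(c(object@alpha, object@beta)))
    cat(sprintf(", alpha = %.3g, beta = %.3g", object@alpha, object@beta))
  cat("]\n")
})

#' @export
setMethod("show", "BlankStatistics", function(object) {
  cat(sprintf("Blank statistics: mean %.4g, sd %.4g (N_b = %d)\n",
              object@mean, object@sd, object@count))
})

#' @export
setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "Calibration curve (%s, n = %d): slope %.4g, intercept %.4g,\n",
    object@weighting, length(object@concentrations), object@slope,
    object@intercept))
  cat(sprintf("  residual SD %.4g, leverage h0 = %.4g\n",
              object@residualSD, leverage(object)))
})

#' @export
setMethod("show", "LimitEstimate", function(object) {
  cat(sprintf("%s [%s, %s%s%s]: %s ppm",
              object@kind, object@method, object@deviation,
              if (object@leverageApplied) ", leverage" else "",
              if (object@adjusted) ", adjusted" else "",
              formatLimit(object)))
  if (!object@valid) cat("  <-", object@reason)
  cat("\n")
})

#' @export
setMethod("show", "SurrogateSeries", function(object) {
  cat(sprintf("Surrogate series [%s", object@provenance))
  if (object@provenance != "PCA")
    cat(sprintf("(%d)", object@nComponents))
  cat(sprintf("]: %d samples (%d blanks)", length(object@values),
              sum(object@isBlank)))
  if (!is.na(object@explainedVariance))
    cat(sprintf(", PC1 explains %.1f%%", 100 * object@explainedVariance))
  cat("\n")
})

#' @export
setMethod("show", "CVSelectionReport", function(object) {
  cat(sprintf(
    "CV selection (%dx %d-fold, seed %d): chosen %d component(s)\n",
    object@repeats, object@folds, object@seed, object@chosen))
  cat("  per-repeat choices:", object@chosenPerRepeat, "\n")
  cat("  mean RMSE:", signif(object@meanRMSE, 3), "\n")
})

#' @export
setMethod("show", "SensorFeatureMatrix", function(object) {
  cat(sprintf("SensorFeatureMatrix: %d sensors x %d samples (%s)\n",
              nrow(object), ncol(object),
              metadata(object)$normalization$method))
  callNextMethod()
})
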