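## Feature extraction: per sensor and sample, the plateau response of the
## sample phase minus the immediately preceding baseline, referenced
## against the day's mean blank response. Subtracting the baseline removes
## within-cycle offsets; subtracting the day's analyte-free (ethanolic
## reference) response removes additive between-day drift.

#' Trailing-window phase mean
#'
#' Mean of the last `nPoints` resistance values of one phase (the plateau,
#' where the liquid-gas equilibrium has settled), per sensor. Traces
#' shorter than the window use all points, with a warning.
#'
#' @param cycle A [MeasurementCycle-class].
#' @param phase phase label (default `"C"`, the sample phase).
#' @param nPoints window length (default 10).
#' @return Named numeric vector, one mean per sensor (ohms).
#' @export
phaseMean <- function(cycle, phase = "C", nPoints = 10) {
  stopifnot(nPoints >= 1)
  if (!phase %in% names(cycle@phases))
    stop("missing phase '", phase, "' in cycle ", cycle@cycleId)
  res <- cycle@phases[[phase]]$resistance
  n <- nrow(res)
  if (n < nPoints)
    warning("phase '", phase, "' of cycle ", cycle@cycleId, " has only ", n,
            " points; using all of them")
  colMeans(res[(max(1, n - nPoints + 1)):n, , drop = FALSE])
}

#' Extract drift-corrected features from measurement cycles
#'
#' For sample i on day d and each sensor, computes the baseline-corrected
#' response `ybar_sample,i - ybar_base,i` (sample-phase plateau mean minus
#' the preceding baseline-phase mean) and subtracts the mean of the same
#' quantity over that day's blank (analyte-free reference) cycles. Blank
#' cycles themselves get features too (their ethanol-mean-centred
#' residuals). Every day must contribute at least one blank.
#'
#' @param cycles list of [MeasurementCycle-class] objects.
#' @param nPoints trailing-window length for the plateau means (default 10).
#' @param basePhase baseline phase label preceding the sample phase
#'   (default `"A"`).
#' @return A raw (unnormalized) [SensorFeatureMatrix-class].
#' @export
extractFeatures <- function(cycles, nPoints = 10, basePhase = "A") {
  stopifnot(length(cycles) >= 1)
  ann <- do.call(rbind, lapply(cycles, function(cy) cy@annotation))
  rownames(ann) <- NULL
  raw <- do.call(rbind, lapply(cycles, function(cy)
    phaseMean(cy, "C", nPoints) - phaseMean(cy, basePhase, nPoints)))
  rownames(raw) <- vapply(cycles, function(cy) cy@cycleId, character(1))
  days <- unique(ann$day)
  noBlank <- days[!vapply(days, function(d)
    any(ann$is_blank & ann$day == d), logical(1))]
  if (length(noBlank))
    stop("configuration error: no blank (analyte-free reference) cycles on ",
         "day(s) ", paste(noBlank, collapse = ", "))
  for (d in days) {
    inDay <- ann$day == d
    blankMean <- colMeans(raw[inDay & ann$is_blank, , drop = FALSE])
    raw[inDay, ] <- sweep(raw[inDay, , drop = FALSE], 2, blankMean)
  }
  SensorFeatureMatrix(raw, ann)
}

#' Reference-correct a raw feature table at the feature level
#'
#' Applies the same day-wise blank-mean subtraction as [extractFeatures()]
#' to features that were produced directly (e.g. by [simulateFeatures()])
#' rather than from traces.
#'
#' @param fm raw [SensorFeatureMatrix-class].
#' @return A [SensorFeatureMatrix-class] with each day's blank-mean
#'   removed per sensor.
#' @export
subtractDayBlankMean <- function(fm) {
  vals <- featureValues(fm)
  ann <- sampleInfo(fm)
  for (d in unique(ann$day)) {
    inDay <- ann$day == d
    if (!any(inDay & ann$is_blank))
      stop("configuration error: no blanks on day ", d)
    blankMean <- colMeans(vals[inDay & ann$is_blank, , drop = FALSE])
    vals[inDay, ] <- sweep(vals[inDay, , drop = FALSE], 2, blankMean)
  }
  SensorFeatureMatrix(vals, ann, normalization = normalization(fm))
}

#' Z-score normalize a feature matrix per sensor
#'
#' Centres each sensor column to mean 0 and scales to sample SD 1
#' (divisor N - 1), storing the per-sensor statistics for the inverse
#' transform and for projecting held-out samples. Zero-variance sensors
#' are an error, or dropped with a warning in lenient mode.
#'
#' @param fm A [SensorFeatureMatrix-class].
#' @param lenient drop zero-variance sensors instead of failing.
#' @return A z-scored [SensorFeatureMatrix-class].
#' @export
zscoreNormalize <- function(fm, lenient = FALSE) {
  vals <- featureValues(fm)
  ctr <- colMeans(vals)
  scl <- apply(vals, 2, sd)
  bad <- scl == 0
  if (any(bad)) {
    if (!lenient)
      stop("zero-variance sensor(s): ",
           paste(colnames(vals)[bad], collapse = ", "))
    warning("dropping zero-variance sensor(s): ",
            paste(colnames(vals)[bad], collapse = ", "))
    vals <- vals[, !bad, drop = FALSE]
    ctr <- ctr[!bad]; scl <- scl[!bad]
  }
  z <- sweep(sweep(vals, 2, ctr), 2, scl, "/")
  SensorFeatureMatrix(z, sampleInfo(fm),
                      normalization = list(method = "zscore", center = ctr,
                                           scale = scl))
}

#' Apply stored z-score statistics to new samples
#'
#' Projects held-out rows onto the scale of an already-normalized training
#' matrix (no re-estimation, so no information leaks from test samples).
#'
#' @param fm raw [SensorFeatureMatrix-class] of new samples.
#' @param reference z-scored [SensorFeatureMatrix-class] whose statistics
#'   are reused (or a normalization list).
#' @return A z-scored [SensorFeatureMatrix-class].
#' @export
applyNormalization <- function(fm, reference) {
  norm <- if (is(reference, "SensorFeatureMatrix")) normalization(reference)
          else reference
  if (norm$method != "zscore") stop("reference is not z-score normalized")
  vals <- featureValues(fm)[, names(norm$center), drop = FALSE]
  z <- sweep(sweep(vals, 2, norm$center), 2, norm$scale, "/")
  SensorFeatureMatrix(z, sampleInfo(fm), normalization = norm)
}

#' Invert z-score normalization
#'
#' @param fm z-scored [SensorFeatureMatrix-class].
#' @return The raw-scale [SensorFeatureMatrix-class].
#' @export
denormalize <- function(fm) {
  norm <- normalization(fm)
  if (norm$method != "zscore") stop("matrix is not z-score normalized")
  vals <- sweep(sweep(featureValues(fm), 2, norm$scale, "*"), 2,
                norm$center, "+")
  SensorFeatureMatrix(vals, sampleInfo(fm))
}
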