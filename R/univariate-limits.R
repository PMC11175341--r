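## Zeroth-order LOD/LOQ machinery: blank statistics, the signal threshold
## y_LOD = xbar_b + k * s_b, calibration-curve forms c_LOD = k * s / m with
## and without the leverage factor, and the intercept-adjusted variant.

#' Blank signal statistics
#'
#' @param values numeric vector of blank (analyte-free) signals, length >= 2.
#' @param perSensorSD optional per-sensor blank SD vector (kept for the
#'   coefficient-vector method).
#' @return A [BlankStatistics-class] with sample mean and sample SD
#'   (divisor N - 1).
#' @export
blankStatistics <- function(values, perSensorSD = numeric()) {
  if (length(values) < 2)
    stop("at least 2 blank values are required to estimate the blank SD")
  new("BlankStatistics", mean = mean(values), sd = sd(values),
      count = length(values), perSensorSD = perSensorSD)
}

#' Signal threshold for detection
#'
#' `y_LOD = xbar_b + k * s_b`: the signal a sample must exceed to be
#' declared distinguishable from the blank.
#'
#' @param blanks A [BlankStatistics-class].
#' @param k A [KFactorSpec-class] (or bare numeric multiplier).
#' @return Threshold in signal units.
#' @export
signalThreshold <- function(blanks, k) {
  blanks@mean + resolveK(k) * blanks@sd
}

resolveK <- function(k) {
  if (is(k, "KFactorSpec")) k@value else as.numeric(k)
}
kindOf <- function(k) if (is(k, "KFactorSpec")) k@purpose else "LOD"
asKSpec <- function(k) {
  if (is(k, "KFactorSpec")) k
  else new("KFactorSpec", alpha = NA_real_, beta = NA_real_,
           distribution = "normal", nBlanks = integer(), purpose = "LOD",
           value = as.numeric(k))
}

#' Fit a univariate calibration line
#'
#' Ordinary or weighted least squares of signal on concentration. WLS
#' weights default to reciprocal per-level replicate variances (pooled
#' across levels when a level has fewer than 3 replicates). The residual
#' standard deviation is always the unweighted
#' `sqrt(sum((y - yhat)^2) / (N - 2))`.
#'
#' @param conc concentrations in ppm (length >= 3, >= 2 distinct values;
#'   blanks, i.e. zeros, are normally included).
#' @param signal observed responses, same length.
#' @param weighting `"OLS"` (default) or `"WLS"`.
#' @param weights optional user weights for WLS (otherwise estimated from
#'   replicate variances per level).
#' @return A [CalibrationCurve-class].
#' @export
fitCalibration <- function(conc, signal, weighting = c("OLS", "WLS"),
                           weights = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(length(conc) == length(signal))
  if (length(conc) < 3) stop("calibration needs at least 3 samples")
  if (length(unique(conc)) < 2)
    stop("degenerate design: all concentrations are equal")
  w <- rep(1, length(conc))
  if (weighting == "WLS") {
    if (is.null(weights)) {
      byLevel <- split(signal, conc)
      vars <- vapply(byLevel, function(v)
        if (length(v) >= 3) var(v) else NA_real_, numeric(1))
      pooled <- mean(vars, na.rm = TRUE)
      if (!is.finite(pooled))
        stop("no level has >= 3 replicates; supply 'weights' explicitly")
      vars[is.na(vars)] <- pooled
      if (any(vars == 0))
        stop("a concentration level has zero replicate variance; ",
             "supply pooled or explicit weights")
      lookup <- setNames(1 / vars, names(byLevel))
      w <- unname(lookup[as.character(conc)])
    } else {
      stopifnot(length(weights) == length(conc), all(weights > 0))
      w <- weights
    }
  }
  fit <- lm(signal ~ conc, weights = w)
  res <- signal - fitted(fit)
  new("CalibrationCurve",
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      residualSD = sqrt(sum(res^2) / (length(conc) - 2)),
      concentrations = as.numeric(conc), signal = as.numeric(signal),
      fitted = as.numeric(fitted(fit)), weighting = weighting, weights = w)
}

## shared validity bookkeeping for concentration-domain limits
limitFlags <- function(value) {
  if (!is.finite(value)) list(valid = FALSE, reason = "non-finite result")
  else if (value <= 0)
    list(valid = FALSE,
         reason = if (value == 0) "degenerate (zero deviation)" else
           "negative LOD")
  else list(valid = TRUE, reason = "")
}

slopeMagnitude <- function(curve) {
  m <- curve@slope
  if (m == 0) stop("no analytical sensitivity: calibration slope is zero")
  if (m < 0)
    warning("negative calibration slope; using |m| (the limit is a magnitude)")
  abs(m)
}

#' Detection limit from the calibration slope
#'
#' `c_LOD = k * s / |m|` with s either the blank SD or the curve's residual
#' SD and m the analytical sensitivity.
#'
#' @param k A [KFactorSpec-class] (or numeric multiplier). A spec with
#'   `purpose = "LOQ"` (k = 10) yields the quantification limit.
#' @param s noise estimate in signal units (>= 0).
#' @param curve A [CalibrationCurve-class].
#' @param deviation label recording which estimator `s` is
#'   (`"s_blank"` or `"RMSE"`).
#' @param method method label carried into the estimate.
#' @return A [LimitEstimate-class] in ppm.
#' @export
lodFromSlope <- function(k, s, curve, deviation = "s_blank",
                         method = "single_sensor") {
  stopifnot(s >= 0)
  value <- resolveK(k) * s / slopeMagnitude(curve)
  fl <- limitFlags(value)
  newLimitEstimate(kindOf(k), value, method, deviation, asKSpec(k),
                   valid = fl$valid, reason = fl$reason)
}

#' Leverage-corrected detection limit
#'
#' Inflates the slope-based limit by the calibration-design leverage
#' `h0 = 1/n + cbar^2 / sum((c_i - cbar)^2)`. Two variants are available:
#' `"as_printed"` applies the linear factor `(1 + h0)`; `"sqrt"` applies
#' `sqrt(1 + h0)` as in the original leverage-corrected uncertainty
#' expression. Both reduce to the plain slope formula as h0 -> 0.
#'
#' @inheritParams lodFromSlope
#' @param variant `"as_printed"` (default) or `"sqrt"`.
#' @return A [LimitEstimate-class] with `leverageApplied = TRUE`.
#' @export
lodWithLeverage <- function(k, s, curve, variant = c("as_printed", "sqrt"),
                            deviation = "RMSE", method = "single_sensor") {
  variant <- match.arg(variant)
  stopifnot(s >= 0)
  h0 <- leverage(curve)
  factor <- if (variant == "as_printed") 1 + h0 else sqrt(1 + h0)
  value <- resolveK(k) * s * factor / slopeMagnitude(curve)
  fl <- limitFlags(value)
  est <- newLimitEstimate(kindOf(k), value, method, deviation, asKSpec(k),
                          leverageApplied = TRUE, valid = fl$valid,
                          reason = fl$reason)
  attr(est, "leverageVariant") <- variant
  est
}

#' Intercept-adjusted detection limit
#'
#' When the low-concentration response rises steeply, the fitted intercept
#' b0 exceeds the blank mean and the plain slope formula overstates the
#' limit. The adjusted limit removes the offset:
#' `c_LOD,adj = (xbar_b + k * s - b0) / m`, i.e. the unadjusted value minus
#' `(b0 - xbar_b) / m`. A non-positive result is returned flagged invalid.
#'
#' @inheritParams lodFromSlope
#' @param blanks A [BlankStatistics-class] providing the blank mean.
#' @return A [LimitEstimate-class] with `adjusted = TRUE`.
#' @export
adjustedLod <- function(k, s, curve, blanks, deviation = "s_blank",
                        method = "single_sensor") {
  stopifnot(s >= 0)
  m <- curve@slope
  if (m == 0) stop("no analytical sensitivity: calibration slope is zero")
  value <- (blanks@mean + resolveK(k) * s - curve@intercept) / m
  fl <- limitFlags(value)
  newLimitEstimate(kindOf(k), value, method, deviation, asKSpec(k),
                   adjusted = TRUE, valid = fl$valid, reason = fl$reason)
}

#' Quantification-limit counterparts
#'
#' Convenience wrappers applying the quantification convention k = 10 to
#' the corresponding detection-limit formula; the result has
#' `kind = "LOQ"`.
#'
#' @inheritParams lodFromSlope
#' @inheritParams lodWithLeverage
#' @return A [LimitEstimate-class] of kind `"LOQ"`.
#' @export
loqFromSlope <- function(s, curve, deviation = "s_blank",
                         method = "single_sensor") {
  lodFromSlope(kFactor(purpose = "LOQ"), s, curve, deviation, method)
}

#' @rdname loqFromSlope
#' @export
loqWithLeverage <- function(s, curve, variant = c("as_printed", "sqrt"),
                            deviation = "RMSE", method = "single_sensor") {
  lodWithLeverage(kFactor(purpose = "LOQ"), s, curve, variant, deviation,
                  method)
}

#' Lowest measured concentration exceeding a signal threshold
#'
#' Groups a univariate signal by nonzero concentration level and returns
#' the smallest level whose replicate mean exceeds `yLOD`. When the lowest
#' nonzero level already exceeds the threshold, the result is a
#' lower-bound censored value (reported "< c_min"); when no level exceeds
#' it, a not-detected sentinel.
#'
#' @param values univariate signals (e.g. PC1 scores), one per sample.
#' @param concentrations true concentrations in ppm, same length.
#' @param yLOD signal threshold (from [signalThreshold()]).
#' @return list with `value` (ppm, `NA` when not detected), `censored`
#'   (`"none"`, `"below_lowest"`, `"not_detected"`), `levelMeans` (named
#'   vector) and `exceeds` (logical per level).
#' @export
lowestExceedingConcentration <- function(values, concentrations, yLOD) {
  stopifnot(length(values) == length(concentrations))
  nz <- concentrations > 0
  if (!any(nz)) stop("design error: no nonzero concentration levels")
  lv <- sort(unique(concentrations[nz]))
  means <- vapply(lv, function(l) mean(values[concentrations == l]),
                  numeric(1))
  names(means) <- format(lv, trim = TRUE)
  exceeds <- means > yLOD
  if (!any(exceeds))
    return(list(value = NA_real_, censored = "not_detected",
                levelMeans = means, exceeds = exceeds))
  idx <- which(exceeds)[1]
  list(value = lv[idx],
       censored = if (idx == 1L) "below_lowest" else "none",
       levelMeans = means, exceeds = exceeds)
}

#' Format a limit estimate the way comparison tables print it
#'
#' @param x A [LimitEstimate-class].
#' @param digits significant digits (default 2).
#' @return Character: `"<0.10"` for lower-bound censored values, `"n.d."`
#'   for the not-detected sentinel, otherwise the rounded value (suffixed
#'   `" (invalid)"` when flagged).
#' @export
formatLimit <- function(x, digits = 2) {
  if (x@censored == "not_detected") return("n.d.")
  v <- signif(x@value, digits)
  out <- if (x@censored == "below_lowest") paste0("<", format(v, trim = TRUE))
         else format(v, trim = TRUE)
  if (!x@valid) out <- paste0(out, " (invalid)")
  out
}
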