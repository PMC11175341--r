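## Surrogate-signal detection limits: reduce the samples x sensors table to
## one value per sample (PC1 scores, or concentrations predicted by PCR /
## PLSR), then apply the univariate blank- and calibration-based formulas.
## Detection limits are invariant under linear transformations of the
## response, which is what licenses the surrogate substitution.

concOf <- function(fm) sampleInfo(fm)$concentration_ppm
blankOf <- function(fm) sampleInfo(fm)$is_blank

requireNormalized <- function(fm) {
  if (normalization(fm)$method != "zscore")
    stop("feature matrix must be z-score normalized first ",
         "(see zscoreNormalize())")
}

#' First-principal-component surrogate signal
#'
#' PC1 scores of the centred feature matrix become the univariate signal.
#' The eigenvector sign is arbitrary, so scores are oriented to correlate
#' non-negatively with concentration, making results independent of the
#' numerical routine's sign convention. A warning is emitted when PC1
#' explains less than `varianceFloor` of the variance — the surrogate is
#' only trustworthy when one component dominates (92-98% in well-behaved
#' sensor-array data).
#'
#' @param fm z-scored [SensorFeatureMatrix-class] with >= 3 samples and
#'   >= 2 sensors.
#' @param varianceFloor explained-variance fraction below which to warn
#'   (default 0.80).
#' @return A [SurrogateSeries-class] with provenance `"PCA"`.
#' @export
pc1Surrogate <- function(fm, varianceFloor = 0.80) {
  requireNormalized(fm)
  vals <- featureValues(fm)
  if (nrow(vals) < 3) stop("need at least 3 samples for PCA")
  if (ncol(vals) < 2) stop("need at least 2 sensors for PCA")
  pca <- prcomp(vals, center = TRUE, scale. = FALSE)
  scores <- pca$x[, 1]
  ev <- pca$sdev[1]^2 / sum(pca$sdev^2)
  conc <- concOf(fm)
  if (sd(scores) > 0 && sd(conc) > 0 && cor(scores, conc) < 0)
    scores <- -scores
  if (ev < varianceFloor)
    warning(sprintf(paste0("PC1 explains only %.1f%% of the variance ",
                           "(floor %.0f%%); the univariate surrogate may ",
                           "be unreliable"), 100 * ev, 100 * varianceFloor))
  new("SurrogateSeries", values = unname(scores), concentrations = conc,
      isBlank = blankOf(fm), provenance = "PCA", nComponents = 1L,
      explainedVariance = ev)
}

#' Threshold-based detection limit on PC1 scores (PCA I)
#'
#' Computes the signal threshold `y_LOD = xbar_b + k * s_b` from the
#' blanks' PC1 scores and returns the smallest measured concentration
#' whose mean score exceeds it. No calibration curve is involved, so only
#' measured levels can be returned: the result may be a "< c_min" bound or
#' a not-detected sentinel.
#'
#' @param series A [SurrogateSeries-class] (typically from
#'   [pc1Surrogate()]) containing >= 2 blanks.
#' @param k A [KFactorSpec-class] or numeric multiplier.
#' @return A [LimitEstimate-class], method `"PCA_I"`, deviation
#'   `"s_blank"`.
#' @export
pcaThresholdLod <- function(series, k) {
  if (sum(series@isBlank) < 2)
    stop("insufficient blanks: PCA I needs >= 2 blank samples")
  bl <- blankStatistics(series@values[series@isBlank])
  hit <- lowestExceedingConcentration(series@values, series@concentrations,
                                      signalThreshold(bl, k))
  newLimitEstimate(kindOf(k), hit$value, "PCA_I", "s_blank", asKSpec(k),
                   valid = !is.na(hit$value),
                   reason = if (is.na(hit$value))
                     "no measured level exceeds the threshold" else "",
                   censored = hit$censored)
}

#' Calibration-based detection limit on PC1 scores (PCA II)
#'
#' Fits an OLS line of the PC1 score on concentration and applies the
#' leverage-corrected formula, with the noise estimated either by the SD
#' of the blanks' scores (`"s_blank"`) or by the line's residual SD
#' (`"RMSE"`).
#'
#' @param series A [SurrogateSeries-class].
#' @param k A [KFactorSpec-class] or numeric multiplier.
#' @param deviation `"s_blank"` or `"RMSE"`.
#' @param variant leverage variant, see [lodWithLeverage()].
#' @return A [LimitEstimate-class], method `"PCA_II"`.
#' @export
pcaCalibrationLod <- function(series, k, deviation = c("s_blank", "RMSE"),
                              variant = c("as_printed", "sqrt")) {
  deviation <- match.arg(deviation)
  variant <- match.arg(variant)
  curve <- fitCalibration(series@concentrations, series@values)
  s <- surrogateDeviation(series, curve, deviation)
  lodWithLeverage(k, s, curve, variant, deviation, method = "PCA_II")
}

surrogateDeviation <- function(series, curve, deviation) {
  if (deviation == "RMSE") return(curve@residualSD)
  if (sum(series@isBlank) < 2)
    stop("insufficient blanks for the s_blank deviation")
  sd(series@values[series@isBlank])
}

## ---- multivariate regression backends -----------------------------------
## PCR: principal-component scores as regressors of concentration.
## PLSR: mixOmics NIPALS partial least squares, regression mode.
## Both return held-out-capable predictors for every component count up to
## ncomp in one fit, which keeps cross-validation cheap.

fitPCR <- function(X, y, ncomp) {
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  ncomp <- min(ncomp, ncol(pca$x))
  scores <- pca$x[, seq_len(ncomp), drop = FALSE]
  fits <- lapply(seq_len(ncomp), function(k)
    lm(y ~ scores[, seq_len(k), drop = FALSE]))
  list(predict = function(newX, k) {
    sc <- sweep(newX, 2, pca$center) %*% pca$rotation[, seq_len(k),
                                                      drop = FALSE]
    cf <- coef(fits[[k]])
    drop(cf[1] + sc %*% cf[-1])
  }, ncomp = ncomp)
}

fitPLSR <- function(X, y, ncomp) {
  colnames(X) <- colnames(X, do.NULL = FALSE, prefix = "V")
  ncomp <- min(ncomp, ncol(X), nrow(X) - 1)
  fit <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                       scale = FALSE)
  list(predict = function(newX, k) {
    colnames(newX) <- colnames(X)
    drop(predict(fit, newX)$predict[, 1, k])
  }, ncomp = ncomp)
}

surrogateBackend <- function(model) {
  switch(model, PCR = fitPCR, PLSR = fitPLSR,
         stop("unknown model '", model, "'; use 'PCR' or 'PLSR'"))
}

#' Predicted-concentration surrogate from PCR or PLSR
#'
#' Fits the multivariate regression of concentration on the full feature
#' matrix and returns the fitted predictions as the univariate surrogate.
#'
#' @param fm z-scored [SensorFeatureMatrix-class].
#' @param model `"PCR"` or `"PLSR"`.
#' @param nComponents latent dimensions to use (see
#'   [selectNComponents()]).
#' @return A [SurrogateSeries-class] of predicted concentrations (ppm).
#' @export
surrogatePredictions <- function(fm, model = c("PLSR", "PCR"),
                                 nComponents = 1L) {
  model <- match.arg(model)
  requireNormalized(fm)
  X <- featureValues(fm)
  maxRank <- min(ncol(X), nrow(X) - 1)
  if (nComponents > maxRank)
    stop("nComponents (", nComponents, ") exceeds the data rank (",
         maxRank, ")")
  fit <- surrogateBackend(model)(X, concOf(fm), nComponents)
  new("SurrogateSeries", values = unname(fit$predict(X, nComponents)),
      concentrations = concOf(fm), isBlank = blankOf(fm),
      provenance = model, nComponents = as.integer(nComponents),
      explainedVariance = NA_real_)
}

#' Detection limit from a multivariate regression surrogate
#'
#' Fits PCR or PLSR on the entire dataset, regresses the predicted on the
#' actual concentration by OLS (slope near 1 for a good model) and applies
#' the leverage-corrected formula on that predicted-vs-actual line. The
#' noise estimate is either the line's residual SD (`"RMSE"`) or the SD of
#' the blanks' predictions (`"s_blank"`).
#'
#' @inheritParams surrogatePredictions
#' @param k A [KFactorSpec-class] or numeric multiplier.
#' @param deviation `"RMSE"` or `"s_blank"`.
#' @param variant leverage variant, see [lodWithLeverage()].
#' @return A [LimitEstimate-class]; the method label records the model
#'   and component count, e.g. `"PLSR(2)"`.
#' @export
regressionSurrogateLod <- function(fm, model = c("PLSR", "PCR"),
                                   nComponents = 1L, k,
                                   deviation = c("RMSE", "s_blank"),
                                   variant = c("as_printed", "sqrt")) {
  model <- match.arg(model)
  deviation <- match.arg(deviation)
  variant <- match.arg(variant)
  series <- surrogatePredictions(fm, model, nComponents)
  curve <- fitCalibration(series@concentrations, series@values)
  s <- surrogateDeviation(series, curve, deviation)
  est <- lodWithLeverage(k, s, curve, variant, deviation,
                         method = sprintf("%s(%d)", model, nComponents))
  est
}

#' Select the number of latent components by repeated stratified CV
#'
#' Stratified 5-fold cross-validation (each concentration level spread as
#' evenly as possible over the folds), repeated 10 times with fresh fold
#' assignments. Per repeat, the chosen component count is the smallest
#' whose mean held-out RMSE is within one standard error of the minimizer
#' (the one-standard-error rule, operationalizing "minimum number of
#' components with high Q2 and low RMSE" without overfitting); the final
#' choice is the median over repeats, ties rounded down for parsimony.
#' Fold models are trained on raw features z-scored with the training
#' fold's statistics only.
#'
#' @param fm raw (unnormalized) [SensorFeatureMatrix-class]; a z-scored
#'   matrix is accepted and used as-is.
#' @param model `"PLSR"` or `"PCR"`.
#' @param folds folds per repeat (default 5).
#' @param repeats CV repetitions (default 10).
#' @param seed RNG seed making the report reproducible.
#' @param candidates candidate counts (default `1:min(10, sensors,
#'   n - 2)`).
#' @return A [CVSelectionReport-class].
#' @export
selectNComponents <- function(fm, model = c("PLSR", "PCR"), folds = 5L,
                              repeats = 10L, seed = 1L,
                              candidates = NULL) {
  model <- match.arg(model)
  Xraw <- featureValues(fm)
  y <- concOf(fm)
  n <- nrow(Xraw)
  if (n < 2 * folds)
    stop("too few samples (", n, ") for ", folds,
         "-fold CV; reduce 'folds'")
  preNormalized <- normalization(fm)$method == "zscore"
  if (is.null(candidates))
    candidates <- seq_len(min(10L, ncol(Xraw), n - 2L))
  candidates <- as.integer(candidates)
  kmax <- max(candidates)
  backend <- surrogateBackend(model)
  rng <- withSeed(seed)
  on.exit(rng(), add = TRUE)

  foldRMSE <- function(train, test) {
    if (preNormalized) {
      Xtr <- Xraw[train, , drop = FALSE]; Xte <- Xraw[test, , drop = FALSE]
    } else {
      ctr <- colMeans(Xraw[train, , drop = FALSE])
      scl <- apply(Xraw[train, , drop = FALSE], 2, sd)
      scl[scl == 0] <- 1
      Xtr <- sweep(sweep(Xraw[train, , drop = FALSE], 2, ctr), 2, scl, "/")
      Xte <- sweep(sweep(Xraw[test, , drop = FALSE], 2, ctr), 2, scl, "/")
    }
    fit <- backend(Xtr, y[train], kmax)
    vapply(candidates, function(k) {
      kk <- min(k, fit$ncomp)
      pred <- fit$predict(Xte, kk)
      err <- y[test] - pred
      c(rmse = sqrt(mean(err^2)),
        q2 = 1 - sum(err^2) / sum((y[test] - mean(y[test]))^2))
    }, numeric(2))
  }

  allRMSE <- array(NA_real_, c(repeats, folds, length(candidates)))
  allQ2 <- allRMSE
  chosenPerRepeat <- integer(repeats)
  for (r in seq_len(repeats)) {
    foldId <- stratifiedFolds(y, folds)
    for (f in seq_len(folds)) {
      test <- which(foldId == f)
      if (!length(test)) next
      m <- foldRMSE(which(foldId != f), test)
      allRMSE[r, f, ] <- m["rmse", ]
      allQ2[r, f, ] <- m["q2", ]
    }
    mr <- matrix(allRMSE[r, , ], nrow = folds)
    meanR <- colMeans(mr, na.rm = TRUE)
    best <- which.min(meanR)
    bestFolds <- mr[, best][!is.na(mr[, best])]
    se <- sd(bestFolds) / sqrt(length(bestFolds))
    chosenPerRepeat[r] <-
      candidates[which(meanR <= meanR[best] + se)[1]]
  }
  med <- median(chosenPerRepeat)
  chosen <- as.integer(floor(med))          # between-integer ties -> floor
  if (!chosen %in% candidates)
    chosen <- candidates[which.min(abs(candidates - chosen))]
  new("CVSelectionReport", candidates = candidates,
      meanRMSE = apply(allRMSE, 3, mean, na.rm = TRUE),
      meanQ2 = apply(allQ2, 3, mean, na.rm = TRUE),
      chosenPerRepeat = chosenPerRepeat, chosen = chosen,
      folds = as.integer(folds), repeats = as.integer(repeats),
      seed = as.integer(seed))
}

## evaluate with a local RNG state; returns a restore function
withSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

## spread each concentration level as evenly as possible over the folds;
## a level with fewer members than folds contributes to that many folds
stratifiedFolds <- function(y, folds) {
  foldId <- integer(length(y))
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    foldId[idx] <- rep_len(sample(folds), length(idx))
  }
  foldId
}

#' Coefficient-vector detection limit
#'
#' Contracts the per-sensor blank SD vector with the multivariate
#' regression coefficient vector: `c_LOD = 3 * s_blank(1xJ) . b(Jx1)`. No
#' surrogate is formed; the coefficients translate sensor noise directly
#' into concentration units. The method can return negative values when
#' sensors with negative coefficients carry large blank SDs — such results
#' are flagged invalid rather than silently dropped.
#'
#' @param blankSD per-sensor blank SD vector (on the same normalized
#'   feature scale as the coefficients).
#' @param coefficients regression coefficient vector, same length.
#' @param k multiplier (default 3, the method's conventional factor).
#' @return A [LimitEstimate-class], method `"coefficient_vector"`.
#' @export
coefficientVectorLod <- function(blankSD, coefficients, k = 3) {
  if (length(blankSD) != length(coefficients))
    stop("blankSD and coefficients must have the same length")
  value <- resolveK(k) * sum(blankSD * coefficients)
  fl <- limitFlags(value)
  newLimitEstimate(kindOf(k), value, "coefficient_vector", "s_blank",
                   asKSpec(k), valid = fl$valid, reason = fl$reason)
}

#' Regression coefficient vector of a fitted surrogate model
#'
#' Recovers the JX1 coefficient vector b such that predictions equal
#' `intercept + X b`, for use with [coefficientVectorLod()].
#'
#' @inheritParams surrogatePredictions
#' @return Named numeric vector of per-sensor coefficients.
#' @export
surrogateCoefficients <- function(fm, model = c("PLSR", "PCR"),
                                  nComponents = 1L) {
  model <- match.arg(model)
  requireNormalized(fm)
  X <- featureValues(fm)
  fit <- surrogateBackend(model)(X, concOf(fm), nComponents)
  ## predictions are linear in X: probe with unit steps around the origin
  J <- ncol(X)
  probe <- rbind(0, diag(J))
  colnames(probe) <- colnames(X)
  p <- fit$predict(probe, min(nComponents, fit$ncomp))
  setNames(p[-1] - p[1], colnames(X))
}

#' Per-sensor blank standard deviations
#'
#' @param fm [SensorFeatureMatrix-class] (normalized or raw).
#' @return Named vector of blank SDs per sensor.
#' @export
perSensorBlankSD <- function(fm) {
  vals <- featureValues(fm)[blankOf(fm), , drop = FALSE]
  if (nrow(vals) < 2) stop("need >= 2 blanks for per-sensor blank SDs")
  apply(vals, 2, sd)
}

#' Mean-relative-error change-point detection limit
#'
#' Heuristic alternative to hypothesis testing: below the detection limit,
#' the mean relative prediction error |yhat - c| / c of a regression model
#' rises sharply. Per ascending nonzero level the MRE (percent) is
#' computed; the limit is the smallest level from which onward all changes
#' between consecutive level MREs stay at or below `threshold` percentage
#' points (a single later jump resets it). Blanks must be excluded — the
#' relative error is undefined at c = 0. With few, widely spaced levels
#' the changes can stay large throughout, so the estimate is flagged
#' unsuitable when 5 or fewer levels are available.
#'
#' @param series A [SurrogateSeries-class] of predicted concentrations
#'   (typically PLSR); must contain >= 3 nonzero levels and no blanks
#'   (subset them away first).
#' @param threshold stabilisation threshold in percentage points
#'   (default 1).
#' @return list with `profile` (an [MREProfile-class]) and `estimate`
#'   (a [LimitEstimate-class], method `"MRE"`).
#' @export
mreLod <- function(series, threshold = 1) {
  if (any(series@concentrations == 0))
    stop("blanks must be excluded: relative error is undefined at c = 0")
  lv <- sort(unique(series@concentrations))
  if (length(lv) < 3) stop("need >= 3 nonzero concentration levels")
  mre <- vapply(lv, function(l) {
    idx <- series@concentrations == l
    100 * mean(abs(series@values[idx] - l) / l)
  }, numeric(1))
  deltas <- abs(diff(mre))
  ok <- deltas <= threshold
  ## deltas[i] is the change into level i+1; the limit is the first level
  ## whose incoming change and all later changes stabilise
  stableFrom <- if (all(ok)) 1L else {
    lastBad <- max(which(!ok))
    if (lastBad == length(deltas)) NA_integer_ else lastBad + 2L
  }
  few <- length(lv) <= 5
  if (is.na(stableFrom)) {
    est <- newLimitEstimate("LOD", NA_real_, "MRE", "RMSE", asKSpec(NA_real_),
                            valid = FALSE,
                            reason = "MRE never stabilises below threshold",
                            censored = "not_detected")
  } else {
    value <- lv[stableFrom]
    est <- newLimitEstimate("LOD", value, "MRE", "RMSE", asKSpec(NA_real_),
                            valid = !few,
                            reason = if (few)
                              "method unsuitable for few, widely spaced levels"
                            else "")
  }
  list(profile = new("MREProfile", levels = lv, mre = mre, deltas = deltas,
                     threshold = threshold),
       estimate = est)
}
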