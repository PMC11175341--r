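surrogate <- function(values, conc, provenance = "PCA") {
  new("SurrogateSeries", values = values, concentrations = conc,
      isBlank = conc == 0, provenance = provenance, nComponents = 1L,
      explainedVariance = NA_real_)
}

test_that("rank-1 data gives explained variance 1 and scores proportional to the latent", {
  latent <- c(0, 0, 0.5, 1, 1.5, 2, 3, 4, 5)
  loadings <- c(2, -1, 0.5, 3)
  X <- outer(latent, loadings) + outer(rep(1, 9), c(5, 6, 7, 8))
  ann <- data.frame(day = 1, substance = "x", concentration_ppm = latent,
                    replicate = 1, is_blank = latent == 0)
  fm <- SensorFeatureMatrix(X, ann)
  z <- zscoreNormalize(fm)
  s <- pc1Surrogate(z)
  expect_equal(s@explainedVariance, 1, tolerance = 1e-12)
  expect_equal(abs(cor(s@values, latent)), 1, tolerance = 1e-12)
  expect_gte(cor(s@values, latent), 0)   # orientation rule
})

test_that("PC1 scores are invariant to the eigenvector sign convention", {
  fm <- normalizedStudy(sensorModel(J = 8), seed = 31)
  s1 <- pc1Surrogate(fm)
  flipped <- SensorFeatureMatrix(-featureValues(fm), sampleInfo(fm),
                                 normalization = normalization(fm))
  s2 <- pc1Surrogate(flipped)
  # negating every loading flips raw scores; orientation undoes it
  expect_equal(abs(s2@values), abs(s1@values), tolerance = 1e-9)
  expect_gte(cor(s2@values, s2@concentrations), 0)
})

test_that("a weak first component triggers the explained-variance warning", {
  set.seed(40)
  X <- matrix(rnorm(40 * 6), 40, 6)
  conc <- rep(c(0, 1, 2, 4), each = 10)
  ann <- data.frame(day = 1, substance = "x", concentration_ppm = conc,
                    replicate = 1, is_blank = conc == 0)
  z <- zscoreNormalize(SensorFeatureMatrix(X, ann))
  expect_warning(pc1Surrogate(z), "explains only")
})

test_that("the threshold method picks the lowest level whose mean score clears y_LOD", {
  s <- surrogate(c(-1, 0, 1, 2, 2, 4, 4), c(0, 0, 0, 1, 1, 2, 2))
  est <- pcaThresholdLod(s, 3)          # blanks {-1,0,1}: y_LOD = 0 + 3*1
  expect_equal(limitValue(est), 2)
  expect_equal(methodLabel(est), "PCA_I")

  low <- pcaThresholdLod(surrogate(c(-1, 0, 1, 9, 9, 10, 10),
                                   c(0, 0, 0, 1, 1, 2, 2)), 3)
  expect_equal(low@censored, "below_lowest")
  expect_equal(formatLimit(low), "<1")

  nd <- pcaThresholdLod(surrogate(c(-1, 0, 1, 1, 1, 2, 2),
                                  c(0, 0, 0, 1, 1, 2, 2)), 3)
  expect_equal(nd@censored, "not_detected")
  expect_false(isValid(nd))

  expect_error(pcaThresholdLod(surrogate(c(1, 2), c(1, 2)), 3),
               "insufficient blanks")
})

test_that("calibration-based surrogate limits are invariant to affine response rescaling", {
  set.seed(55)
  conc <- rep(c(0, 0.25, 0.5, 1, 2), each = 4)
  vals <- 1.7 * conc + rnorm(length(conc), sd = 0.2)
  for (tr in list(c(1, 0), c(3.2, -7), c(-0.4, 11))) {
    a <- surrogate(vals, conc)
    b <- surrogate(tr[1] * vals + tr[2], conc)
    for (dev in c("s_blank", "RMSE")) {
      la <- limitValue(suppressWarnings(pcaCalibrationLod(a, 3.3, dev)))
      lb <- limitValue(suppressWarnings(pcaCalibrationLod(b, 3.3, dev)))
      expect_equal(la, lb, tolerance = 1e-9)
    }
  }
})

test_that("noiseless linear surrogates collapse to a degenerate zero limit", {
  conc <- rep(c(0, 1, 2), each = 3)
  est <- pcaCalibrationLod(surrogate(2 * conc, conc), 3.3, "RMSE")
  expect_lt(limitValue(est), 1e-10)
})

test_that("regression surrogates recover truth on noiseless single-latent data", {
  model <- sensorModel(J = 6, commonFactorWeight = 1, noiseSD = 0,
                       dayDriftSD = 0, saturation = 1e9)
  fm <- normalizedStudy(model, seed = 2)
  for (m in c("PLSR", "PCR")) {
    s <- surrogatePredictions(fm, m, 1)
    expect_equal(s@values, s@concentrations, tolerance = 1e-6)
    est <- regressionSurrogateLod(fm, m, 1, 3.3, "RMSE")
    expect_lt(limitValue(est), 1e-6)
  }
})

test_that("surrogate model limits are invariant to per-sensor affine feature changes", {
  model <- sensorModel(J = 6)
  raw <- subtractDayBlankMean(simulateFeatures(model, studyDesign(seed = 8)))
  scaled <- SensorFeatureMatrix(
    sweep(sweep(featureValues(raw), 2, seq(2, 12, length.out = 6), "*"),
          2, seq(-3, 3, length.out = 6), "+"),
    sampleInfo(raw))
  for (m in c("PLSR", "PCR")) {
    l1 <- limitValue(regressionSurrogateLod(zscoreNormalize(raw), m, 1,
                                            3.3, "RMSE"))
    l2 <- limitValue(regressionSurrogateLod(zscoreNormalize(scaled), m, 1,
                                            3.3, "RMSE"))
    expect_equal(l1, l2, tolerance = 1e-9)
  }
})

test_that("component-count overflow and the chosen-provenance label are handled", {
  fm <- normalizedStudy(sensorModel(J = 4), seed = 3)
  expect_error(surrogatePredictions(fm, "PLSR", 40), "exceeds the data rank")
  est <- regressionSurrogateLod(fm, "PLSR", 2, 3.3, "RMSE")
  expect_equal(methodLabel(est), "PLSR(2)")
})

test_that("cross-validated selection is deterministic under a fixed seed", {
  fm <- simulateFeatures(rank1Model(J = 8), studyDesign(seed = 14))
  r1 <- selectNComponents(fm, "PCR", seed = 99, candidates = 1:4)
  r2 <- selectNComponents(fm, "PCR", seed = 99, candidates = 1:4)
  expect_identical(r1@chosenPerRepeat, r2@chosenPerRepeat)
  expect_identical(r1@meanRMSE, r2@meanRMSE)
  expect_identical(r1@chosen, r2@chosen)
})

test_that("one-SE selection finds the constructed latent dimensionality", {
  f1 <- simulateFeatures(rank1Model(), studyDesign(seed = 6))
  expect_equal(selectNComponents(f1, "PLSR", seed = 6,
                                 candidates = 1:6)@chosen, 1L)
  f2 <- simulateFeatures(rank2Model(), studyDesign(seed = 6))
  expect_equal(selectNComponents(f2, "PLSR", seed = 6,
                                 candidates = 1:6)@chosen, 2L)
})

test_that("the coefficient-vector method reduces to the slope formula for one sensor", {
  # signal = m*c: coefficient b = 1/m, so 3 * s_b * b = 3 * s_b / m
  m <- 2.5; sB <- 0.4
  est <- coefficientVectorLod(sB, 1 / m)
  expect_equal(limitValue(est), 3 * sB / m)
  expect_equal(methodLabel(est), "coefficient_vector")

  neg <- coefficientVectorLod(c(5, 0.1), c(-1, 2))
  expect_false(isValid(neg))
  expect_match(reason(neg), "negative")

  zero <- coefficientVectorLod(c(0, 0), c(1, 2))
  expect_false(isValid(zero))
  expect_error(coefficientVectorLod(c(1, 2), 1), "same length")
})

test_that("extracted model coefficients reproduce the fitted predictions", {
  fm <- normalizedStudy(sensorModel(J = 5), seed = 17)
  for (m in c("PLSR", "PCR")) {
    b <- surrogateCoefficients(fm, m, 2)
    s <- surrogatePredictions(fm, m, 2)
    X <- featureValues(fm)
    # predictions are affine in X with slope vector b
    recon <- unname(drop(X %*% b))
    expect_equal(recon - mean(recon), s@values - mean(s@values),
                 tolerance = 1e-8)
  }
  sds <- perSensorBlankSD(fm)
  expect_length(sds, 5)
  expect_true(all(sds > 0))
})

test_that("the MRE change-point rule matches its definition", {
  lv <- 1:5
  mre <- c(70, 7, 2, 1.5, 1.2)    # deltas 63, 5, 0.5, 0.3
  conc <- rep(lv, each = 2)
  pred <- rep(lv * (1 + mre / 100), each = 2)
  out <- mreLod(surrogate(pred, conc, "PLSR"))
  expect_equal(out$profile@deltas, c(63, 5, 0.5, 0.3), tolerance = 1e-9)
  expect_equal(limitValue(out$estimate), 4)
  # five levels only: flagged unsuitable even though a value exists
  expect_false(isValid(out$estimate))
  expect_match(reason(out$estimate), "unsuitable")
})

test_that("MRE boundary and failure paths behave", {
  lv <- c(1, 2, 4, 8, 16, 32)
  stable <- rep(10 + c(0, 0.5, 0.2, 0.4, 0.1, 0.3), 1)
  pred <- lv * (1 + stable / 100)
  out <- mreLod(surrogate(pred, lv, "PLSR"))
  expect_equal(limitValue(out$estimate), 1)      # all deltas <= 1
  expect_true(isValid(out$estimate))             # 6 levels: usable

  wild <- lv * (1 + c(90, 60, 30, 15, 8, 4) / 100)
  nd <- mreLod(surrogate(wild, lv, "PLSR"))
  expect_equal(nd$estimate@censored, "not_detected")

  expect_error(mreLod(surrogate(c(0, 1, 2), c(0, 1, 2))), "blanks")
  expect_error(mreLod(surrogate(c(1, 2), c(1, 2))), ">= 3")
})
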