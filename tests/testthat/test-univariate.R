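test_that("k-factor resolution enforces its preconditions", {
  expect_error(kFactor(0.05, 0.05, "student_t"), "nBlanks")
  expect_error(kFactor(0.01, 0.05, "student_t", nBlanks = 9),
               "alpha == beta")
  expect_error(kFactor(0.6, 0.05), "0, 0.5")
  expect_equal(kFactor(purpose = "LOQ")@value, 10)
  expect_equal(kFactor(purpose = "LOQ")@purpose, "LOQ")
})

test_that("blank statistics use the sample SD with divisor N - 1", {
  b <- blankStatistics(c(5, 5, 5))
  expect_equal(c(b@mean, b@sd), c(5, 0))
  b2 <- blankStatistics(c(1, 2, 3))
  expect_equal(c(b2@mean, b2@sd), c(2, 1))
  expect_equal(b2@count, 3L)
  expect_error(blankStatistics(4), "at least 2")
})

test_that("the signal threshold is blank mean plus k times blank SD", {
  expect_equal(signalThreshold(blankStatistics(c(9, 10, 11)), 3.3),
               10 + 3.3 * 1)
  expect_equal(signalThreshold(blankStatistics(c(5, 5, 5)), 3.3), 5)
  expect_equal(signalThreshold(blankStatistics(c(1, 2, 3)), 3), 5)
})

test_that("calibration fitting recovers exact lines and stores leverage ingredients", {
  curve <- fitCalibration(c(0, 1, 2), 2 * c(0, 1, 2) + 1)
  expect_equal(curve@slope, 2)
  expect_equal(curve@intercept, 1)
  expect_equal(curve@residualSD, 0, tolerance = 1e-12)
  expect_equal(leverage(curve), 1 / 3 + 1 / 2)
  expect_error(fitCalibration(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("equal-weight WLS coincides with OLS", {
  set.seed(4)
  conc <- rep(c(0, 1, 2, 4), each = 3)
  sig <- 1.5 * conc + rnorm(12)
  ols <- fitCalibration(conc, sig)
  wls <- fitCalibration(conc, sig, "WLS", weights = rep(2, 12))
  expect_equal(wls@slope, ols@slope, tolerance = 1e-10)
  expect_equal(wls@intercept, ols@intercept, tolerance = 1e-10)
})

test_that("reciprocal-variance WLS beats OLS under heteroscedastic noise", {
  set.seed(7)
  conc <- rep(c(0, 1, 2, 4, 8), each = 4)
  slopes <- replicate(400, {
    sig <- 2 * conc + rnorm(length(conc), sd = 1 + conc)
    c(fitCalibration(conc, sig)@slope,
      fitCalibration(conc, sig, "WLS")@slope)
  })
  expect_lt(var(slopes[2, ]), var(slopes[1, ]))
})

test_that("slope-based detection limits follow k * s / |m|", {
  curve <- fitCalibration(c(0, 1, 2), 2 * c(0, 1, 2) + 1)
  est <- lodFromSlope(3.3, 1, curve)
  expect_equal(limitValue(est), 1.65)
  expect_true(isValid(est))

  degenerate <- lodFromSlope(3.3, 0, curve)
  expect_equal(limitValue(degenerate), 0)
  expect_false(isValid(degenerate))

  # negative slopes are handled by magnitude, with a warning
  down <- fitCalibration(c(0, 1, 2), -2 * c(0, 1, 2) + 1)
  expect_warning(estNeg <- lodFromSlope(3.3, 1, down), "negative")
  expect_equal(limitValue(estNeg), 1.65)
})

test_that("detection limits are scale invariant and the threshold shift-equivariant", {
  set.seed(12)
  conc <- rep(c(0, 0.5, 1, 2, 4), each = 3)
  sig <- 1.2 * conc + rnorm(length(conc), sd = 0.3)
  for (gamma in c(0.1, 10, 250)) {
    a <- fitCalibration(conc, sig)
    b <- fitCalibration(conc, gamma * sig)
    expect_equal(limitValue(lodFromSlope(3.3, a@residualSD, a, "RMSE")),
                 limitValue(lodFromSlope(3.3, b@residualSD, b, "RMSE")),
                 tolerance = 1e-9)
    expect_equal(limitValue(lodWithLeverage(3.3, a@residualSD, a)),
                 limitValue(lodWithLeverage(3.3, b@residualSD, b)),
                 tolerance = 1e-9)
    # additive shifts leave slope-based limits unchanged too
    d <- fitCalibration(conc, sig + gamma)
    expect_equal(limitValue(lodFromSlope(3.3, d@residualSD, d, "RMSE")),
                 limitValue(lodFromSlope(3.3, a@residualSD, a, "RMSE")),
                 tolerance = 1e-9)
    # ... while the signal threshold moves by exactly the shift
    bl <- blankStatistics(sig[conc == 0])
    bl2 <- blankStatistics(sig[conc == 0] + gamma)
    expect_equal(signalThreshold(bl2, 3.3) - signalThreshold(bl, 3.3),
                 gamma, tolerance = 1e-9)
  }
})

test_that("the leverage correction matches hand evaluation and vanishes for huge designs", {
  curve <- fitCalibration(c(0, 1, 2), c(0, 1, 2))   # slope 1
  h0 <- 1 / 3 + 1 / 2
  expect_equal(limitValue(lodWithLeverage(3.3, 1, curve, "as_printed")),
               3.3 * (1 + h0))                       # 6.05
  expect_equal(limitValue(lodWithLeverage(3.3, 1, curve, "sqrt")),
               3.3 * sqrt(1 + h0))                   # 4.468
  # centred, large design: h0 -> 0 and the leverage form approaches Eq. 3
  big <- fitCalibration(seq(-1, 1, length.out = 2000),
                        seq(-1, 1, length.out = 2000))
  expect_equal(limitValue(lodWithLeverage(3.3, 1, big, "as_printed")),
               limitValue(lodFromSlope(3.3, 1, big)), tolerance = 1e-3)
})

test_that("leverage is always at least 1/n, and larger with uncentred designs", {
  set.seed(5)
  for (i in 1:25) {
    conc <- c(0, sort(runif(sample(3:10, 1), 0, 5)))
    curve <- fitCalibration(conc, 2 * conc + rnorm(length(conc), sd = 0.1))
    expect_gte(leverage(curve), 1 / length(conc))
  }
  # blanks included and positive levels: cbar > 0 so strictly greater
  conc <- rep(c(0, 1, 2), each = 3)
  curve <- fitCalibration(conc, conc)
  expect_gt(leverage(curve), 1 / length(conc))
})

test_that("the adjusted limit removes the intercept/blank-mean offset", {
  conc <- c(0, 1, 2)
  curve <- fitCalibration(conc, conc + 2)            # slope 1, intercept 2
  blanks <- blankStatistics(c(0.9, 1.0, 1.1))        # mean 1
  est <- adjustedLod(3, 1, curve, blanks)            # (1 + 3 - 2) / 1 = 2
  expect_equal(limitValue(est), 2)
  expect_true(est@adjusted)

  # intercept equal to the blank mean: adjustment is a no-op
  curve0 <- fitCalibration(conc, conc + 1)
  expect_equal(limitValue(adjustedLod(3, 1, curve0, blanks)),
               limitValue(lodFromSlope(3, 1, curve0)))

  # intercept far above the blank threshold: flagged invalid
  curveHi <- fitCalibration(conc, conc + 50)
  bad <- adjustedLod(3, 1, curveHi, blanks)
  expect_false(isValid(bad))
  expect_match(reason(bad), "negative")
})

test_that("quantification limits are the same formulas at k = 10", {
  curve <- fitCalibration(c(0, 1, 2), 2 * c(0, 1, 2))
  loq <- loqFromSlope(1, curve)
  expect_equal(limitValue(loq), 5)
  expect_equal(loq@kind, "LOQ")
  # LOQ / LOD = 10 / k for a shared deviation and slope
  kLOD <- kFactor(0.05, 0.05)
  expect_equal(limitValue(loq) / limitValue(lodFromSlope(kLOD, 1, curve)),
               10 / kLOD@value, tolerance = 1e-12)
  # proportionality survives the leverage factor
  expect_equal(limitValue(loqWithLeverage(1, curve)),
               limitValue(lodWithLeverage(kLOD, 1, curve)) * 10 / kLOD@value,
               tolerance = 1e-12)
})

test_that("lowest exceeding concentration reports hits, bounds and sentinels", {
  vals <- c(0, 0, 1, 1, 5, 5)
  conc <- c(0, 0, 1, 1, 2, 2)
  hit <- lowestExceedingConcentration(vals, conc, yLOD = 3)
  expect_equal(hit$value, 2)
  expect_equal(hit$censored, "none")

  none <- lowestExceedingConcentration(vals, conc, yLOD = 100)
  expect_true(is.na(none$value))
  expect_equal(none$censored, "not_detected")

  low <- lowestExceedingConcentration(vals, conc, yLOD = 0.5)
  expect_equal(low$value, 1)
  expect_equal(low$censored, "below_lowest")

  expect_error(lowestExceedingConcentration(c(1, 2), c(0, 0), 1),
               "design error")
})

test_that("comparison-table formatting mirrors the censoring conventions", {
  k <- kFactor(0.05, 0.05)
  curve <- fitCalibration(c(0, 1, 2), c(0, 1, 2))
  est <- lodFromSlope(k, 0.031, curve)
  expect_equal(formatLimit(est), "0.1")
  est@censored <- "below_lowest"
  expect_equal(formatLimit(est), "<0.1")
  est@censored <- "not_detected"
  expect_equal(formatLimit(est), "n.d.")
})
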