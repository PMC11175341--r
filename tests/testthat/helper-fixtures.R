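## Fixtures built in code: hand-sized cycles, simulated studies, and the
## simulate -> segment -> extract chain used by several files.

## one measurement cycle with constant plateaus per sensor
makeCycle <- function(id, day, conc, replicate, baseline, sample,
                      nPoints = 12, sensors = names(baseline)) {
  stopifnot(length(baseline) == length(sample))
  if (is.null(sensors)) sensors <- sprintf("S%02d", seq_along(baseline))
  mkPhase <- function(levels) {
    m <- matrix(rep(levels, each = nPoints), nPoints, length(levels))
    colnames(m) <- sensors
    list(time = seq_len(nPoints), resistance = m)
  }
  new("MeasurementCycle", cycleId = id,
      phases = list(B = mkPhase(baseline), A = mkPhase(baseline),
                    C = mkPhase(sample)),
      annotation = data.frame(day = day, substance = "test",
                              concentration_ppm = conc,
                              replicate = replicate,
                              is_blank = conc == 0))
}

## segment all recordings of a simulateTraces() result into cycles
cyclesFromTraces <- function(tr, schedule = c(B = 30, A = 30, C = 60),
                             strict = FALSE) {
  unlist(lapply(tr$recordings, function(r)
    segmentCycles(r, schedule, tr$annotations[tr$annotations$day == r@day, ,
                                              drop = FALSE],
                  strict = strict)),
    recursive = FALSE)
}

## default-style study, reference-corrected and z-scored
normalizedStudy <- function(model, seed = 1, design = studyDesign(seed = seed)) {
  zscoreNormalize(subtractDayBlankMean(simulateFeatures(model, design)))
}

## pure rank-1 and rank-2 (two latent factors) small studies for CV tests;
## the response is kept in its linear regime so the constructed rank IS
## the predictive dimensionality
rank1Model <- function(J = 16) {
  sensorModel(J = J, commonFactorWeight = 1, dayDriftSD = 0,
              noiseSD = 0.2, saturation = 1e6)
}
rank2Model <- function(J = 16) {
  sensorModel(J = J, commonFactorWeight = 0.5, dayDriftSD = 0,
              noiseSD = 0.2, saturation = 1e6, nuisanceSD = 0.5)
}

## unbiasing constant of the sample SD: E[s] = c4(df) * sigma
c4 <- function(df) sqrt(2 / df) * exp(lgamma((df + 1) / 2) - lgamma(df / 2))
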