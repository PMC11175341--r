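## Synthetic electronic-nose studies: a saturating (Michaelis-Menten-type)
## multi-sensor response with additive per-(day, sensor) drift, a shared
## latent signal channel, optional heteroscedastic noise, and brute-force
## detection-limit oracles. Defaults reproduce the reference study design:
## 5 concentration levels including the blank, 3 days, 3 replicates per
## level per day = 45 samples with 9 blanks, and a dominant first
## principal component (92-98% explained variance).

#' Construct a sensor-array response model
#'
#' See [SensorModelSpec-class] for the response equation. Defaults: 62
#' sensors with sensitivities spread deterministically over 0.5-1.5
#' signal/ppm, saturation scale 5 ppm (quasi-linear below ~1 ppm), blank
#' noise SD 0.07, homoscedastic, mild additive day drift (SD 0.02) and a
#' 0.95 common-factor weight.
#'
#' @param J sensor count.
#' @param sensitivity per-sensor slope a_s, recycled to length J.
#' @param saturation kappa_s in ppm, recycled.
#' @param noiseSD sigma0_s, recycled.
#' @param hetero lambda, SD growth per ppm.
#' @param dayDriftSD tau.
#' @param commonFactorWeight w, fraction of structure carried by the
#'   concentration channel.
#' @param nuisanceLoading per-sensor loading on the nuisance factor,
#'   recycled (default: reversed sensitivity spread).
#' @param nuisanceSD SD of the shared per-sample nuisance factor.
#' @return A [SensorModelSpec-class].
#' @export
sensorModel <- function(J = 62L, sensitivity = seq(0.5, 1.5, length.out = J),
                        saturation = 5, noiseSD = 0.07, hetero = 0,
                        dayDriftSD = 0.02, commonFactorWeight = 0.95,
                        nuisanceLoading = rev(seq(0.5, 1.5, length.out = J)),
                        nuisanceSD = 0.3) {
  new("SensorModelSpec", J = as.integer(J),
      sensitivity = rep_len(sensitivity, J),
      saturation = rep_len(saturation, J),
      noiseSD = rep_len(noiseSD, J), hetero = hetero,
      dayDriftSD = dayDriftSD, commonFactorWeight = commonFactorWeight,
      nuisanceLoading = rep_len(nuisanceLoading, J),
      nuisanceSD = nuisanceSD)
}

#' Construct a study design
#'
#' @param levels concentration levels in ppm, including 0.
#' @param days measurement days.
#' @param replicatesPerDay replicates of every level on each day.
#' @param seed RNG seed.
#' @return A [StudyDesign-class]. The default gives 45 samples, 9 blanks.
#' @export
studyDesign <- function(levels = c(0, 0.1, 0.25, 0.5, 1), days = 3L,
                        replicatesPerDay = 3L, seed = 1L) {
  new("StudyDesign", levels = as.numeric(levels), days = as.integer(days),
      replicatesPerDay = as.integer(replicatesPerDay),
      seed = as.integer(seed))
}

## noiseless mean response at concentration c (drift and nuisance excluded)
meanResponseGeneral <- function(model, c) {
  sat <- matrix(model@saturation, length(c), model@J, byrow = TRUE)
  cc <- matrix(c, length(c), model@J)
  model@commonFactorWeight *
    (cc / (1 + cc / sat)) *
    matrix(model@sensitivity, length(c), model@J, byrow = TRUE)
}

designTable <- function(design) {
  ann <- expand.grid(replicate = seq_len(design@replicatesPerDay),
                     concentration_ppm = design@levels,
                     day = seq_len(design@days))
  ann <- ann[order(ann$day, ann$concentration_ppm, ann$replicate), ]
  rownames(ann) <- NULL
  ann$substance <- "synthetic"
  ann$is_blank <- ann$concentration_ppm == 0
  ann[, c("day", "substance", "concentration_ppm", "replicate", "is_blank")]
}

#' Simulate a feature-level synthetic study
#'
#' Draws the raw (pre-normalization, pre-reference-correction) feature of
#' every (sample, sensor) cell: saturating mean response + shared nuisance
#' factor + per-(day, sensor) drift offset + heteroscedastic noise.
#' Deterministic under the design seed.
#'
#' @param model A [SensorModelSpec-class].
#' @param design A [StudyDesign-class].
#' @return A raw [SensorFeatureMatrix-class] (apply
#'   [subtractDayBlankMean()] and [zscoreNormalize()] before surrogate
#'   analysis).
#' @export
simulateFeatures <- function(model, design) {
  restore <- withSeed(design@seed)
  on.exit(restore(), add = TRUE)
  ann <- designTable(design)
  n <- nrow(ann)
  mu <- meanResponseGeneral(model, ann$concentration_ppm)
  drift <- matrix(rnorm(design@days * model@J, sd = model@dayDriftSD),
                  design@days, model@J)
  eta <- rnorm(n, sd = model@nuisanceSD)
  nuis <- (1 - model@commonFactorWeight) * outer(eta, model@nuisanceLoading)
  sdMat <- matrix(model@noiseSD, n, model@J, byrow = TRUE) +
    model@hetero * matrix(ann$concentration_ppm, n, model@J)
  eps <- matrix(rnorm(n * model@J), n, model@J) * sdMat
  vals <- mu + nuis + drift[ann$day, , drop = FALSE] + eps
  colnames(vals) <- sprintf("S%02d", seq_len(model@J))
  rownames(vals) <- sprintf("d%02d_c%03d", ann$day, seq_len(n))
  SensorFeatureMatrix(vals, ann)
}

#' Simulate day-level trace recordings
#'
#' Builds per-day resistance time series whose cycles reproduce a
#' feature-level simulation exactly: phase A and B sit at a per-(day,
#' sensor) baseline level and phase C plateaus at baseline + the raw
#' feature value, so [segmentCycles()] + [extractFeatures()] on the output
#' recover [simulateFeatures()]'s values after reference correction.
#' Plateaus are stationary (the sample-level noise is already in the
#' feature value), keeping the trailing-window means exact.
#'
#' @param model A [SensorModelSpec-class].
#' @param design A [StudyDesign-class].
#' @param schedule named phase durations in seconds (default
#'   `c(B = 30, A = 30, C = 60)`).
#' @param baselineLevel nominal sensor resistance in ohms (default 1e5).
#' @param samplingInterval seconds between points (default 1).
#' @return list with `recordings` (list of [DayRecording-class]),
#'   `annotations` (data.frame) and `features` (the underlying raw
#'   [SensorFeatureMatrix-class]).
#' @export
simulateTraces <- function(model, design, schedule = c(B = 30, A = 30, C = 60),
                           baselineLevel = 1e5, samplingInterval = 1) {
  fm <- simulateFeatures(model, design)
  vals <- featureValues(fm)
  ann <- sampleInfo(fm)
  ppp <- round(schedule / samplingInterval)
  cycleLen <- sum(ppp)
  phaseOfPoint <- rep(names(schedule), ppp)
  recordings <- lapply(seq_len(design@days), function(d) {
    rows <- which(ann$day == d)
    nPts <- length(rows) * cycleLen
    mat <- matrix(baselineLevel, nPts, model@J)
    for (j in seq_along(rows)) {
      idxC <- (j - 1) * cycleLen + which(phaseOfPoint == "C")
      mat[idxC, ] <- baselineLevel +
        matrix(vals[rows[j], ], length(idxC), model@J, byrow = TRUE)
    }
    colnames(mat) <- colnames(vals)
    new("DayRecording", day = d,
        time = seq(0, by = samplingInterval, length.out = nPts),
        resistance = mat, boundaries = data.frame())
  })
  list(recordings = recordings, annotations = ann, features = fm)
}

#' Brute-force detection-limit oracle
#'
#' Ground truth for a simulated study, independent of the estimation
#' pipeline. For the chosen univariate channel — one sensor, or the
#' optimal linear combination of all sensors (`"latent"`, with effective
#' sensitivity-to-noise `sqrt(sum((w a_s / sigma0_s)^2))`) — the
#' low-concentration closed form is `k * sigma_eff / m_eff`. It is
#' cross-checked by Monte Carlo: blank replicate groups of the design's
#' blank count are drawn, each yields a blank-SD-based limit, and the mean
#' and standard error over groups are reported (the group mean carries the
#' finite-sample SD bias c4(N_b), which the closed form does not).
#'
#' @param model A [SensorModelSpec-class] with `noiseSD > 0`.
#' @param design A [StudyDesign-class] (supplies the blank count).
#' @param k multiplier or [KFactorSpec-class].
#' @param target `"latent"` (optimal combination) or `"sensor"`.
#' @param sensor sensor index when `target = "sensor"`.
#' @param replicates Monte-Carlo blank groups (default 2000; each group
#'   has the design's blank count, so >= 10^4 blank draws by default).
#' @param seed RNG seed for the Monte-Carlo part.
#' @return list with `trueLod` (closed form, ppm), `monteCarlo` (mean of
#'   the group estimates), `se` (its standard error), `kUsed`,
#'   `replicates` and `agreementZ` (standardized difference after c4
#'   correction).
#' @export
oracleLod <- function(model, design, k, target = c("latent", "sensor"),
                      sensor = 1L, replicates = 2000L, seed = 1L) {
  target <- match.arg(target)
  kv <- resolveK(k)
  w <- model@commonFactorWeight
  if (target == "sensor") {
    m <- w * model@sensitivity[sensor]
    sigma <- model@noiseSD[sensor]
  } else {
    snr2 <- sum((w * model@sensitivity / model@noiseSD)^2)
    if (snr2 == 0) stop("zero sensitivity: the oracle is undefined")
    m <- sqrt(snr2)            # on the noise-whitened channel sigma = 1
    sigma <- 1
  }
  if (m == 0) stop("zero sensitivity: the oracle is undefined")
  if (sigma == 0) stop("oracle requires noiseSD > 0")
  trueLod <- kv * sigma / m
  nb <- design@days * design@replicatesPerDay
  restore <- withSeed(seed)
  on.exit(restore(), add = TRUE)
  draws <- matrix(rnorm(replicates * nb, sd = sigma), replicates, nb)
  ests <- kv * apply(draws, 1, sd) / m
  mc <- mean(ests)
  se <- sd(ests) / sqrt(replicates)
  c4 <- sqrt(2 / (nb - 1)) * gamma(nb / 2) / gamma((nb - 1) / 2)
  list(trueLod = trueLod, monteCarlo = mc, se = se, kUsed = kv,
       replicates = replicates, blanksPerGroup = nb,
       agreementZ = (mc - c4 * trueLod) / se)
}

#' Saturation-corrected oracle concentration
#'
#' Solves `m c / (1 + c / kappa) = k * sigma` for the concentration whose
#' mean response reaches the detection threshold under the saturating
#' response; reduces to `k sigma / m` as kappa grows.
#'
#' @param model A [SensorModelSpec-class].
#' @param k multiplier.
#' @param sensor sensor index.
#' @return Concentration in ppm (`Inf` when the threshold exceeds the
#'   saturation plateau).
#' @export
oracleLodSaturating <- function(model, k, sensor = 1L) {
  kv <- resolveK(k)
  m <- model@commonFactorWeight * model@sensitivity[sensor]
  sigma <- model@noiseSD[sensor]
  kappa <- model@saturation[sensor]
  y <- kv * sigma
  denom <- m - y / kappa
  if (denom <= 0) return(Inf)
  y / denom
}
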