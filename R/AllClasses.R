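## Central S4 containers. The feature table rides on SummarizedExperiment
## (sensors = rows, samples = columns) so annotations, subsetting and
## metadata bookkeeping come from the Bioconductor stack.

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

annotationColumns <- c("day", "substance", "concentration_ppm",
                       "replicate", "is_blank")

#' SensorFeatureMatrix: samples x sensors feature table
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one
#' drift-corrected feature value per (sensor, sample): rows are sensors,
#' columns are samples. `colData` carries the sample annotations (`day`,
#' `substance`, `concentration_ppm`, `replicate`, `is_blank`); metadata
#' element `normalization` records whether columns are raw (ohms) or
#' z-scored per sensor (dimensionless), together with the per-sensor centre
#' and scale needed for the inverse transform and for projecting held-out
#' samples.
#'
#' @slot normalization stored in `metadata()`: a list with elements
#'   `method` (`"none"` or `"zscore"`) and, for z-scored data, numeric
#'   vectors `center` and `scale` (sample SD, divisor N-1) named by sensor.
#' @export
setClass("SensorFeatureMatrix", contains = "SummarizedExperiment")

setValidity("SensorFeatureMatrix", function(object) {
  msg <- character()
  cd <- colData(object)
  missing <- setdiff(annotationColumns, colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("missing annotation column(s): ",
                         paste(missing, collapse = ", ")))
  if (!length(msg)) {
    conc <- cd$concentration_ppm
    if (any(conc < 0)) msg <- c(msg, "negative concentration")
    if (!all(cd$is_blank == (conc == 0)))
      msg <- c(msg, "is_blank must hold exactly when concentration_ppm == 0")
  }
  norm <- metadata(object)$normalization
  if (is.null(norm) || !norm$method %in% c("none", "zscore"))
    msg <- c(msg, "metadata()$normalization$method must be 'none' or 'zscore'")
  else if (norm$method == "zscore" && any(norm$scale <= 0))
    msg <- c(msg, "stored z-score scales must all be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorFeatureMatrix
#'
#' @param values numeric matrix, samples in rows and sensors in columns
#'   (transposed internally to the sensors-by-samples layout).
#' @param annotation data.frame with one row per sample and columns
#'   `day`, `substance`, `concentration_ppm`, `replicate`, `is_blank`.
#' @param normalization normalization state list (default: raw).
#' @return A [SensorFeatureMatrix-class].
#' @export
SensorFeatureMatrix <- function(values, annotation,
                                normalization = list(method = "none")) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(annotation))
    stop("row count of 'values' (samples) must equal annotation rows")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample_%03d", seq_len(nrow(values)))
  annotation$is_blank <- as.logical(annotation$is_blank)
  se <- SummarizedExperiment(
    assays = list(features = t(values)),
    colData = DataFrame(annotation, row.names = rownames(values)),
    metadata = list(normalization = normalization))
  new("SensorFeatureMatrix", se)
}

#' Feature values as a samples x sensors matrix
#' @param fm A [SensorFeatureMatrix-class].
#' @return Numeric matrix, one row per sample, one column per sensor.
#' @export
featureValues <- function(fm) t(assay(fm, "features"))

#' Sample annotations as a data.frame
#' @param fm A [SensorFeatureMatrix-class].
#' @return data.frame with one row per sample.
#' @export
sampleInfo <- function(fm) as.data.frame(colData(fm))

#' Sensor identifiers
#' @param fm A [SensorFeatureMatrix-class].
#' @return Character vector of sensor ids (row names of the assay).
#' @export
sensorIds <- function(fm) rownames(fm)

#' Normalization state of a feature matrix
#' @param fm A [SensorFeatureMatrix-class].
#' @return The normalization list (`method`, and `center`/`scale` when
#'   z-scored).
#' @export
normalization <- function(fm) metadata(fm)$normalization

#' k-factor specification for detection/quantification decisions
#'
#' Resolves the multiplier k applied to a noise estimate. For detection
#' (`purpose = "LOD"`) under normality, `k = z(1-alpha) + z(1-beta)`; the
#' IUPAC alpha = beta = 0.05 gives 3.29 (usually printed 3.3). For few blank
#' replicates the symmetric Student-t form `k = 2 * t(1-alpha, N_b - 1)` is
#' used (3.72 for 9 blanks). For quantification (`purpose = "LOQ"`) k is the
#' reciprocal of the acceptable relative precision, 10 by convention.
#'
#' @slot alpha,beta false-alarm and miss probabilities (in (0, 0.5)).
#' @slot distribution `"normal"` or `"student_t"`.
#' @slot nBlanks blank replicate count N_b (Student-t only).
#' @slot purpose `"LOD"` or `"LOQ"`.
#' @slot value resolved multiplier.
#' @export
setClass("KFactorSpec", representation(
  alpha = "numeric", beta = "numeric", distribution = "character",
  nBlanks = "integer", purpose = "character", value = "numeric"))

setValidity("KFactorSpec", function(object) {
  msg <- character()
  if (object@purpose == "LOD" && !anyNA(c(object@alpha, object@beta))) {
    if (any(c(object@alpha, object@beta) <= 0) ||
        any(c(object@alpha, object@beta) >= 0.5))
      msg <- c(msg, "alpha and beta must lie in (0, 0.5)")
  }
  if (!object@distribution %in% c("normal", "student_t"))
    msg <- c(msg, "distribution must be 'normal' or 'student_t'")
  if (object@distribution == "student_t" &&
      (length(object@nBlanks) != 1L || object@nBlanks < 2L))
    msg <- c(msg, "student_t requires nBlanks >= 2")
  if (!object@purpose %in% c("LOD", "LOQ"))
    msg <- c(msg, "purpose must be 'LOD' or 'LOQ'")
  if (length(msg)) msg else TRUE
})

#' Blank-sample signal statistics
#'
#' Mean and sample standard deviation (divisor N-1) of analyte-free
#' measurements; these anchor the detection decision.
#'
#' @slot mean blank mean signal.
#' @slot sd blank sample SD.
#' @slot count number of blank replicates.
#' @slot perSensorSD optional per-sensor blank SD vector (coefficient-vector
#'   method).
#' @export
setClass("BlankStatistics", representation(
  mean = "numeric", sd = "numeric", count = "integer",
  perSensorSD = "numeric"))

setValidity("BlankStatistics", function(object) {
  if (object@sd < 0) "sd must be >= 0" else TRUE
})

#' Univariate calibration line
#'
#' Least-squares line of signal on concentration with the ingredients of
#' leverage-corrected detection-limit formulas: slope (analytical
#' sensitivity), intercept, residual standard deviation with N-2 degrees of
#' freedom, and the concentration design.
#'
#' @slot slope analytical sensitivity m (signal per ppm).
#' @slot intercept fitted intercept b0 (signal units).
#' @slot residualSD `sqrt(sum((y - yhat)^2) / (N - 2))`.
#' @slot concentrations calibration concentrations c_i (ppm).
#' @slot signal observed responses y_i.
#' @slot fitted fitted responses yhat_i.
#' @slot weighting `"OLS"` or `"WLS"`.
#' @slot weights regression weights (all 1 for OLS).
#' @export
setClass("CalibrationCurve", representation(
  slope = "numeric", intercept = "numeric", residualSD = "numeric",
  concentrations = "numeric", signal = "numeric", fitted = "numeric",
  weighting = "character", weights = "numeric"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  n <- length(object@concentrations)
  if (n < 3) msg <- c(msg, "calibration needs n >= 3 samples")
  if (length(unique(object@concentrations)) < 2)
    msg <- c(msg, "calibration needs >= 2 distinct concentrations")
  if (object@residualSD < 0) msg <- c(msg, "residualSD must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("leverage", "CalibrationCurve", function(x) {
  ci <- x@concentrations
  1 / length(ci) + mean(ci)^2 / sum((ci - mean(ci))^2)
})

#' One detection- or quantification-limit estimate
#'
#' @slot kind `"LOD"` or `"LOQ"`.
#' @slot value limit in ppm (`NA` for the not-detected sentinel).
#' @slot method estimator label (`"single_sensor"`, `"PCA_I"`, `"PCA_II"`,
#'   `"PCR"`, `"PLSR"`, `"coefficient_vector"`, `"MRE"`).
#' @slot deviation noise estimator used (`"s_blank"` or `"RMSE"`).
#' @slot k the [KFactorSpec-class] applied.
#' @slot leverageApplied whether the leverage factor entered the formula.
#' @slot adjusted whether the intercept-vs-blank-mean correction was applied.
#' @slot valid usability flag; `FALSE` carries a `reason`.
#' @slot reason why the estimate is flagged (empty when valid).
#' @slot censored `"none"`, `"below_lowest"` (reported as "< c_min") or
#'   `"not_detected"` (no measured level exceeded the threshold).
#' @export
setClass("LimitEstimate", representation(
  kind = "character", value = "numeric", method = "character",
  deviation = "character", k = "KFactorSpec", leverageApplied = "logical",
  adjusted = "logical", valid = "logical", reason = "character",
  censored = "character"))

setValidity("LimitEstimate", function(object) {
  msg <- character()
  if (!object@kind %in% c("LOD", "LOQ")) msg <- c(msg, "kind must be LOD/LOQ")
  if (!object@censored %in% c("none", "below_lowest", "not_detected"))
    msg <- c(msg, "bad censoring state")
  if (isTRUE(object@valid) && !is.na(object@value) && object@value <= 0)
    msg <- c(msg, "a valid estimate must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("limitValue", "LimitEstimate", function(x) x@value)
setMethod("isValid", "LimitEstimate", function(x) x@valid)
setMethod("reason", "LimitEstimate", function(x) x@reason)
setMethod("methodLabel", "LimitEstimate", function(x) x@method)

## internal constructor with defaults
newLimitEstimate <- function(kind, value, method, deviation, k,
                             leverageApplied = FALSE, adjusted = FALSE,
                             valid = TRUE, reason = "", censored = "none") {
  new("LimitEstimate", kind = kind, value = value, method = method,
      deviation = deviation, k = k, leverageApplied = leverageApplied,
      adjusted = adjusted, valid = valid, reason = reason,
      censored = censored)
}

#' Univariate surrogate signal aligned to true concentrations
#'
#' Either first-principal-component scores or the concentrations predicted
#' by a multivariate regression; the stand-in that makes classical
#' univariate detection-limit formulas applicable to array data.
#'
#' @slot values surrogate value per sample (PC1 score, or predicted ppm).
#' @slot concentrations true concentration per sample (ppm).
#' @slot isBlank blank flag per sample.
#' @slot provenance `"PCA"`, `"PCR"` or `"PLSR"`.
#' @slot nComponents latent dimensions used (1 for PCA).
#' @slot explainedVariance PC1 explained-variance fraction (PCA only, else
#'   `NA`).
#' @export
setClass("SurrogateSeries", representation(
  values = "numeric", concentrations = "numeric", isBlank = "logical",
  provenance = "character", nComponents = "integer",
  explainedVariance = "numeric"))

setValidity("SurrogateSeries", function(object) {
  n <- length(object@values)
  if (length(object@concentrations) != n || length(object@isBlank) != n)
    "values, concentrations and isBlank must have equal length" else TRUE
})

#' Cross-validation report for latent-dimension selection
#'
#' @slot candidates candidate component counts.
#' @slot meanRMSE mean held-out RMSE per candidate (ppm), averaged over all
#'   repeats and folds.
#' @slot meanQ2 mean held-out Q2 per candidate.
#' @slot chosenPerRepeat component count chosen by the one-standard-error
#'   rule in each repeat.
#' @slot chosen final choice: median over repeats, ties rounded down.
#' @slot folds,repeats,seed CV configuration.
#' @export
setClass("CVSelectionReport", representation(
  candidates = "integer", meanRMSE = "numeric", meanQ2 = "numeric",
  chosenPerRepeat = "integer", chosen = "integer", folds = "integer",
  repeats = "integer", seed = "integer"))

setValidity("CVSelectionReport", function(object) {
  msg <- character()
  if (!object@chosen %in% object@candidates)
    msg <- c(msg, "chosen must be a candidate")
  if (any(object@meanRMSE < 0)) msg <- c(msg, "RMSE must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Mean-relative-error profile over concentration levels
#'
#' @slot levels ascending nonzero concentration levels (ppm).
#' @slot mre mean relative prediction error per level (percent).
#' @slot deltas absolute change between consecutive level MREs (percentage
#'   points), aligned to `levels[-1]`.
#' @slot threshold stabilisation threshold (percentage points, default 1).
#' @export
setClass("MREProfile", representation(
  levels = "numeric", mre = "numeric", deltas = "numeric",
  threshold = "numeric"))

setValidity("MREProfile", function(object) {
  msg <- character()
  if (any(object@levels <= 0)) msg <- c(msg, "levels must be positive")
  if (is.unsorted(object@levels, strictly = TRUE))
    msg <- c(msg, "levels must be strictly ascending")
  if (any(object@mre < 0)) msg <- c(msg, "mre must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One day's raw multi-sensor recording
#'
#' @slot day integer day index.
#' @slot time sampling times in seconds, 0-based within the day, strictly
#'   increasing.
#' @slot resistance time x sensors matrix of resistances (ohms, > 0),
#'   column names are sensor ids.
#' @slot boundaries data.frame of cycle/phase intervals (`cycle`, `phase`,
#'   `start`, `end` as row indices into `time`), filled by
#'   [segmentCycles()].
#' @export
setClass("DayRecording", representation(
  day = "integer", time = "numeric", resistance = "matrix",
  boundaries = "data.frame"))

setValidity("DayRecording", function(object) {
  msg <- character()
  if (length(object@time) != nrow(object@resistance))
    msg <- c(msg, "time and resistance rows must match")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (any(object@resistance <= 0)) msg <- c(msg, "resistances must be > 0")
  if (length(msg)) msg else TRUE
})

#' One sample's phase-resolved measurement cycle
#'
#' Phases follow the instrument schedule: B (flush of sensor and sample
#' vessel), A (baseline, sensor-only flush) and C (headspace sample
#' measurement, mandatory).
#'
#' @slot cycleId identifier, unique within a study.
#' @slot phases named list; each element a list with `time` (seconds) and
#'   `resistance` (time x sensors matrix). All phases share the sensor set;
#'   `"C"` must be present.
#' @slot annotation one-row data.frame with `day`, `substance`,
#'   `concentration_ppm`, `replicate`, `is_blank`.
#' @export
setClass("MeasurementCycle", representation(
  cycleId = "character", phases = "list", annotation = "data.frame"))

setValidity("MeasurementCycle", function(object) {
  msg <- character()
  if (!"C" %in% names(object@phases))
    msg <- c(msg, "sample phase 'C' must be present")
  ids <- lapply(object@phases, function(p) colnames(p$resistance))
  if (length(unique(ids)) > 1)
    msg <- c(msg, "all phases must share the same sensor set")
  if (!all(annotationColumns %in% colnames(object@annotation)))
    msg <- c(msg, "annotation lacks required columns")
  if (length(msg)) msg else TRUE
})

#' Synthetic sensor-array response model
#'
#' Per sample at concentration c (ppm), day d and sensor s the raw feature
#' is `w * a_s * c / (1 + c / kappa_s) + (1 - w) * b_s * eta_i + delta_{d,s}
#' + eps`, with saturating (Michaelis-Menten-type) response that is
#' quasi-linear at low concentration, a shared latent nuisance factor eta,
#' additive per-(day, sensor) drift delta ~ N(0, tau^2) and noise
#' eps ~ N(0, (sigma0_s + lambda * c)^2).
#'
#' @slot J sensor count.
#' @slot sensitivity per-sensor low-concentration slope a_s (signal/ppm).
#' @slot saturation kappa_s (ppm), concentration scale of the nonlinearity.
#' @slot noiseSD sigma0_s, signal SD at c = 0.
#' @slot hetero lambda, SD growth per ppm (0 = homoscedastic).
#' @slot dayDriftSD tau, SD of additive per-(day, sensor) offsets.
#' @slot commonFactorWeight w in [0, 1]: fraction of structured signal
#'   carried by the concentration-driven latent channel.
#' @slot nuisanceLoading per-sensor loading b_s on the nuisance factor.
#' @slot nuisanceSD SD of the per-sample nuisance factor eta.
#' @export
setClass("SensorModelSpec", representation(
  J = "integer", sensitivity = "numeric", saturation = "numeric",
  noiseSD = "numeric", hetero = "numeric", dayDriftSD = "numeric",
  commonFactorWeight = "numeric", nuisanceLoading = "numeric",
  nuisanceSD = "numeric"))

setValidity("SensorModelSpec", function(object) {
  msg <- character()
  if (any(!is.finite(object@sensitivity))) msg <- c(msg, "non-finite sensitivity")
  if (any(object@saturation <= 0)) msg <- c(msg, "saturation must be > 0")
  if (any(object@noiseSD < 0) || object@dayDriftSD < 0 ||
      object@hetero < 0 || object@nuisanceSD < 0)
    msg <- c(msg, "noise/drift SDs must be >= 0")
  if (object@commonFactorWeight < 0 || object@commonFactorWeight > 1)
    msg <- c(msg, "commonFactorWeight must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic study design
#'
#' Defaults mirror a dilution-series study: 5 concentration levels
#' including the blank, 3 measurement days, each level measured 3 times per
#' day, giving 45 samples of which 9 are blanks.
#'
#' @slot levels concentration levels in ppm, must include 0 (the blank).
#' @slot days number of measurement days.
#' @slot replicatesPerDay replicates of each level per day.
#' @slot seed RNG seed for reproducible simulation.
#' @export
setClass("StudyDesign", representation(
  levels = "numeric", days = "integer", replicatesPerDay = "integer",
  seed = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (!0 %in% object@levels) msg <- c(msg, "levels must include the blank (0)")
  if (any(object@levels < 0)) msg <- c(msg, "levels must be >= 0")
  if (object@days < 1 || object@replicatesPerDay < 1)
    msg <- c(msg, "days and replicatesPerDay must be >= 1")
  if (length(msg)) msg else TRUE
})
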