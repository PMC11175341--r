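## Reading and writing the instrument-facing plain-text formats: day-level
## recordings (one timestamp column + one resistance column per sensor),
## sample annotation tables, and the extracted feature table.

#' Read a day-level sensor recording
#'
#' Expects a delimited text file with a header row: a time column (seconds,
#' strictly increasing, 0-based within the day) followed by one numeric
#' resistance column per sensor. Decimal points only; files using decimal
#' commas fail validation rather than being silently misread.
#'
#' @param path file path.
#' @param day integer day index attached to the recording.
#' @param sep field separator (default ",").
#' @param timeColumn name of the time column (default "time").
#' @return A [DayRecording-class].
#' @export
readDayRecording <- function(path, day = 1L, sep = ",",
                             timeColumn = "time") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!timeColumn %in% colnames(df))
    stop("format error: missing time column '", timeColumn, "' in ", path)
  sensorCols <- setdiff(colnames(df), timeColumn)
  if (length(sensorCols) < 1)
    stop("format error: no sensor columns in ", path)
  for (cn in c(timeColumn, sensorCols)) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(is.na(num) & !is.na(v)))
        stop("format error: non-numeric values in column '", cn, "'")
      df[[cn]] <- num
    }
    if (anyNA(df[[cn]]))
      stop("format error: missing values in column '", cn, "'")
  }
  tm <- df[[timeColumn]]
  if (is.unsorted(tm, strictly = TRUE))
    stop("format error: time column is not strictly increasing ",
         "(duplicate or out-of-order timestamps)")
  res <- as.matrix(df[sensorCols])
  if (any(res <= 0))
    stop("format error: non-positive resistance values")
  new("DayRecording", day = as.integer(day), time = tm, resistance = res,
      boundaries = data.frame())
}

#' Write a day recording to CSV
#'
#' Inverse of [readDayRecording()]; numbers are written at full precision.
#'
#' @param rec A [DayRecording-class].
#' @param path output file path.
#' @param sep field separator.
#' @param timeColumn header for the time column.
#' @return `path`, invisibly.
#' @export
writeDayRecording <- function(rec, path, sep = ",", timeColumn = "time") {
  df <- data.frame(rec@time, rec@resistance, check.names = FALSE)
  colnames(df) <- c(timeColumn, colnames(rec@resistance))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Columns: `day`, `substance`, `concentration_ppm`, `replicate`,
#' `is_blank` and optionally `cycle_id`.
#'
#' @param path CSV file path.
#' @return data.frame with validated types (`is_blank` logical and
#'   consistent with `concentration_ppm == 0`).
#' @export
readAnnotations <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(annotationColumns, colnames(ann))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  ann$is_blank <- as.logical(ann$is_blank)
  if (!all(ann$is_blank == (ann$concentration_ppm == 0)))
    stop("annotation inconsistency: is_blank must hold exactly when ",
         "concentration_ppm == 0")
  ann
}

#' Segment a day recording into measurement cycles
#'
#' Tiles the recording with the repeating phase schedule (e.g. flush B,
#' baseline A, sample C) and attaches sample annotations. Cycles are joined
#' to annotation rows by order within the day (samples are measured in
#' ascending concentration); an explicit `cycle_id` column in the
#' annotation table overrides order-based joining.
#'
#' @param rec A [DayRecording-class].
#' @param schedule named numeric vector of phase durations in seconds, in
#'   cycle order, e.g. `c(B = 30, A = 30, C = 60)`; must contain `"C"`.
#' @param annotations data.frame of annotations for this day (one row per
#'   expected cycle, in measurement order).
#' @param strict if `TRUE`, a trailing partial cycle is an error; by
#'   default it is dropped with a warning.
#' @return list of [MeasurementCycle-class] objects.
#' @export
segmentCycles <- function(rec, schedule, annotations, strict = FALSE) {
  stopifnot(all(schedule > 0))
  if (!"C" %in% names(schedule))
    stop("schedule must contain the sample phase 'C'")
  dt <- stats::median(diff(rec@time))
  ppp <- round(schedule / dt)              # points per phase
  if (any(ppp < 1)) stop("phase durations shorter than the sampling interval")
  cycleLen <- sum(ppp)
  nPoints <- length(rec@time)
  nCycles <- nPoints %/% cycleLen
  if (nPoints %% cycleLen != 0) {
    if (strict)
      stop("recording does not tile into whole cycles (", nPoints,
           " points, cycle length ", cycleLen, ")")
    warning("dropping trailing partial cycle (",
            nPoints - nCycles * cycleLen, " points)")
  }
  if (nCycles < 1) stop("recording shorter than one cycle")
  if (nrow(annotations) != nCycles)
    stop("annotation mismatch: ", nrow(annotations), " annotation rows for ",
         nCycles, " cycles on day ", rec@day)
  if ("cycle_id" %in% colnames(annotations) &&
      !anyNA(annotations$cycle_id)) {
    ord <- order(annotations$cycle_id)
    annotations <- annotations[ord, , drop = FALSE]
  }
  phaseNames <- names(schedule)
  offsets <- c(0, cumsum(ppp))
  lapply(seq_len(nCycles), function(i) {
    base <- (i - 1) * cycleLen
    phases <- lapply(seq_along(phaseNames), function(p) {
      idx <- (base + offsets[p] + 1):(base + offsets[p + 1])
      list(time = rec@time[idx],
           resistance = rec@resistance[idx, , drop = FALSE])
    })
    names(phases) <- phaseNames
    ann <- annotations[i, annotationColumns, drop = FALSE]
    id <- if ("cycle_id" %in% colnames(annotations))
      as.character(annotations$cycle_id[i])
    else sprintf("d%02d_c%03d", rec@day, i)
    new("MeasurementCycle", cycleId = id, phases = phases, annotation = ann)
  })
}

#' Write a feature matrix to CSV (with a normalization sidecar)
#'
#' Layout: `cycle_id`, the annotation columns, then one column per sensor.
#' When the matrix is z-scored, the per-sensor centres and scales are
#' written to `<path>.norm.json` so held-out samples can be projected onto
#' the same scale.
#'
#' @param fm A [SensorFeatureMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(fm, path) {
  vals <- featureValues(fm)
  df <- cbind(data.frame(cycle_id = rownames(vals)), sampleInfo(fm),
              as.data.frame(vals))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  norm <- normalization(fm)
  if (norm$method == "zscore")
    jsonlite::write_json(
      list(method = "zscore", center = as.list(norm$center),
           scale = as.list(norm$scale)),
      paste0(path, ".norm.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureTable()]
#'
#' @param path CSV path; a `<path>.norm.json` sidecar, if present, restores
#'   the z-score normalization state.
#' @return A [SensorFeatureMatrix-class].
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("cycle_id", annotationColumns)
  sensorCols <- setdiff(colnames(df), meta)
  vals <- as.matrix(df[sensorCols])
  rownames(vals) <- df$cycle_id
  norm <- list(method = "none")
  sidecar <- paste0(path, ".norm.json")
  if (file.exists(sidecar)) {
    js <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    norm <- list(method = js$method, center = unlist(js$center),
                 scale = unlist(js$scale))
  }
  SensorFeatureMatrix(vals, df[annotationColumns], normalization = norm)
}
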