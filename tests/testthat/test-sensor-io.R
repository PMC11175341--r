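test_that("a day CSV parses into one trace per sensor with rows preserved", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,S01,S02", "0,100,200", "1,101,201", "2,102,202"), p)
  rec <- readDayRecording(p)
  expect_equal(dim(rec@resistance), c(3L, 2L))
  expect_equal(colnames(rec@resistance), c("S01", "S02"))
  expect_equal(rec@time, c(0, 1, 2))
  expect_equal(rec@resistance[, "S02"], c(200, 201, 202))
})

test_that("malformed day files are rejected, not silently misread", {
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,S01", "0,100", "0,101"), dup)
  expect_error(readDayRecording(dup), "strictly increasing")

  noTime <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,S01", "0,100"), noTime)
  expect_error(readDayRecording(noTime), "time column 'time'")

  alpha <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,S01", "0,100", "1,abc"), alpha)
  expect_error(readDayRecording(alpha), "non-numeric.*S01")

  # decimal commas inside a semicolon-separated file must fail validation
  commas <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time;S01", "0;100,5", "1;101,5"), commas)
  expect_error(readDayRecording(commas, sep = ";"), "non-numeric")
})

test_that("a simulated day file round-trips through CSV within 1e-9", {
  tr <- simulateTraces(sensorModel(J = 3), studyDesign(seed = 11))
  p <- withr::local_tempfile(fileext = ".csv")
  writeDayRecording(tr$recordings[[2]], p)
  back <- readDayRecording(p, day = 2)
  expect_lt(max(abs(back@resistance - tr$recordings[[2]]@resistance)), 1e-9)
  expect_equal(back@time, tr$recordings[[2]]@time)
})

test_that("segmentation tiles the recording into annotated cycles", {
  ann <- data.frame(day = 1, substance = "x", concentration_ppm = c(0, 1),
                    replicate = c(1, 1), is_blank = c(TRUE, FALSE))
  sched <- c(B = 2, A = 2, C = 3)
  mat <- matrix(100 + seq_len(14), ncol = 1, dimnames = list(NULL, "S01"))
  rec <- new("DayRecording", day = 1L, time = 0:13, resistance = mat,
             boundaries = data.frame())
  cycles <- segmentCycles(rec, sched, ann)
  expect_length(cycles, 2)
  expect_true(all(vapply(cycles, function(cy)
    all(c("B", "A", "C") %in% names(cy@phases)), logical(1))))
  expect_equal(cycles[[1]]@annotation$is_blank, TRUE)
  # concatenating phase slices in order reconstructs the day exactly
  rebuilt <- do.call(rbind, unlist(lapply(cycles, function(cy)
    lapply(cy@phases, `[[`, "resistance")), recursive = FALSE))
  expect_identical(unname(rebuilt), unname(mat))
})

test_that("a trailing partial cycle is dropped with warning, or an error in strict mode", {
  ann <- data.frame(day = 1, substance = "x", concentration_ppm = c(0, 1),
                    replicate = 1, is_blank = c(TRUE, FALSE))
  mat <- matrix(rep(100, 17), ncol = 1, dimnames = list(NULL, "S01"))
  rec <- new("DayRecording", day = 1L, time = 0:16, resistance = mat,
             boundaries = data.frame())
  sched <- c(B = 2, A = 2, C = 3)
  expect_warning(cycles <- segmentCycles(rec, sched, ann), "partial cycle")
  expect_length(cycles, 2)
  expect_error(segmentCycles(rec, sched, ann, strict = TRUE), "tile")
})

test_that("annotation/cycle count mismatches are caught", {
  ann <- data.frame(day = 1, substance = "x", concentration_ppm = 0,
                    replicate = 1, is_blank = TRUE)
  mat <- matrix(rep(100, 14), ncol = 1, dimnames = list(NULL, "S01"))
  rec <- new("DayRecording", day = 1L, time = 0:13, resistance = mat,
             boundaries = data.frame())
  expect_error(segmentCycles(rec, c(B = 2, A = 2, C = 3), ann),
               "annotation mismatch")
})

test_that("a simulated study yields exactly the designed cycle count", {
  design <- studyDesign(levels = c(0, 0.5), days = 2L,
                        replicatesPerDay = 2L, seed = 3)
  tr <- simulateTraces(sensorModel(J = 2), design)
  cycles <- cyclesFromTraces(tr)
  expect_length(cycles, 2 * 2 * 2)    # days x levels x replicates
})

test_that("feature tables round-trip with their normalization sidecar", {
  fm <- normalizedStudy(sensorModel(J = 4), seed = 5)
  p <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(fm, p)
  withr::defer(unlink(paste0(p, ".norm.json")))
  back <- readFeatureTable(p)
  expect_equal(featureValues(back), featureValues(fm), tolerance = 1e-8)
  expect_equal(normalization(back)$method, "zscore")
  expect_equal(normalization(back)$scale, normalization(fm)$scale,
               tolerance = 1e-8)
  expect_equal(sampleInfo(back)$concentration_ppm,
               sampleInfo(fm)$concentration_ppm)
})

test_that("annotation tables enforce the blank/concentration consistency", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(day = 1, substance = "x", concentration_ppm = 1,
                       replicate = 1, is_blank = TRUE), p, row.names = FALSE)
  expect_error(readAnnotations(p), "is_blank")
})
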