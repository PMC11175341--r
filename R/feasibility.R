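## Feasibility assessment: compare estimated limits against bundled
## odor-threshold and in-beer concentration reference ranges for key beer
## volatiles.

#' Bundled beer-volatile reference ranges
#'
#' Human odor threshold values (OTV, in bottom-fermented beer) and typical
#' in-beer concentration ranges, in ppm, for six key fermentation
#' volatiles. Shipped as plain CSV (`extdata/beer_reference_compounds.csv`)
#' and user-overridable.
#'
#' @param path optional CSV with columns `compound`, `otv_low`,
#'   `otv_high`, `beer_low`, `beer_high` to use instead of the bundled
#'   table.
#' @return data.frame of reference constants.
#' @export
referenceCompounds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "beer_reference_compounds.csv",
                        package = "enoseLOD", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Feasibility report against reference ranges
#'
#' For each compound, compares its LOD and LOQ against the OTV interval
#' and the in-beer concentration interval. Verdict rule (stated here so it
#' can be audited): a compound is "suitable for end-of-process monitoring"
#' when its LOD is strictly below the OTV lower bound AND strictly below
#' the upper end of the in-beer concentration range. Comparisons are
#' strict: a limit exactly equal to a bound does not pass.
#'
#' @param estimates data.frame with columns `compound`, `lod` and
#'   optionally `loq` (ppm; `NA` allowed).
#' @param refs reference table from [referenceCompounds()]; compound
#'   matching is case-insensitive.
#' @return data.frame with the numeric comparisons, the four flags
#'   (`lod_below_otv_low`, `lod_below_beer_high`, `loq_below_otv_low`,
#'   `loq_below_beer_high`), a `verdict` and a one-line `narrative`;
#'   compounds absent from the reference table are listed with verdict
#'   `"no reference data"`.
#' @export
feasibilityReport <- function(estimates, refs = referenceCompounds()) {
  stopifnot(all(c("compound", "lod") %in% colnames(estimates)))
  if (!"loq" %in% colnames(estimates)) estimates$loq <- NA_real_
  out <- lapply(seq_len(nrow(estimates)), function(i) {
    cmp <- estimates$compound[i]
    lod <- estimates$lod[i]; loq <- estimates$loq[i]
    j <- match(tolower(cmp), tolower(refs$compound))
    if (is.na(j))
      return(data.frame(compound = cmp, lod = lod, loq = loq,
                        otv_low = NA, otv_high = NA, beer_low = NA,
                        beer_high = NA, lod_below_otv_low = NA,
                        lod_below_beer_high = NA, loq_below_otv_low = NA,
                        loq_below_beer_high = NA,
                        verdict = "no reference data",
                        narrative = paste0(cmp, ": no reference data")))
    r <- refs[j, ]
    f <- list(lod_otv = isTRUE(lod < r$otv_low),
              lod_beer = isTRUE(lod < r$beer_high),
              loq_otv = isTRUE(loq < r$otv_low),
              loq_beer = isTRUE(loq < r$beer_high))
    suitable <- f$lod_otv && f$lod_beer
    data.frame(
      compound = cmp, lod = lod, loq = loq,
      otv_low = r$otv_low, otv_high = r$otv_high,
      beer_low = r$beer_low, beer_high = r$beer_high,
      lod_below_otv_low = f$lod_otv, lod_below_beer_high = f$lod_beer,
      loq_below_otv_low = f$loq_otv, loq_below_beer_high = f$loq_beer,
      verdict = if (suitable) "suitable" else
        "not suitable for end-of-process monitoring",
      narrative = sprintf(
        "%s: LOD %.3g ppm vs OTV [%.3g, %.3g] and in-beer [%.3g, %.3g] -> %s",
        cmp, lod, r$otv_low, r$otv_high, r$beer_low, r$beer_high,
        if (suitable) "suitable" else "not suitable"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
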