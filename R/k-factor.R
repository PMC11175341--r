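#' Resolve the detection/quantification multiplier k
#'
#' The detection decision declares a sample distinguishable from the blank
#' when its signal exceeds the blank mean by k times a noise estimate. Under
#' normality and homoscedasticity, `k = z(1 - alpha) + z(1 - beta)`; the
#' IUPAC-recommended alpha = beta = 0.05 yields 3.29 (commonly printed as
#' 3.3), and the frequent simplification k = 3 corresponds to error
#' probabilities of about 0.07 (see [errorProbability()]). When the blank SD
#' rests on few replicates, the symmetric Student-t form
#' `k = 2 * t(1 - alpha, N_b - 1)` is appropriate: 3.72 for 9 blanks. For
#' quantification the convention k = 10 (reciprocal of a 10% acceptable
#' relative SD) replaces the detection factor.
#'
#' @param alpha false-alarm probability (blank called analyte).
#' @param beta miss probability (analyte called blank).
#' @param distribution `"normal"` or `"student_t"`.
#' @param nBlanks blank replicate count N_b; required for `"student_t"`
#'   (degrees of freedom N_b - 1).
#' @param purpose `"LOD"` (default) or `"LOQ"`; for `"LOQ"` the resolved
#'   value is fixed at `loqK` regardless of the probabilities.
#' @param loqK quantification multiplier, default 10.
#' @return A [KFactorSpec-class]; the resolved multiplier is in `@value`
#'   (unrounded; round only for display).
#' @examples
#' kFactor(0.05, 0.05)                                  # 3.2897
#' kFactor(0.05, 0.05, "student_t", nBlanks = 9)        # 3.7191
#' kFactor(purpose = "LOQ")                             # 10
#' @export
kFactor <- function(alpha = 0.05, beta = 0.05,
                    distribution = c("normal", "student_t"),
                    nBlanks = NULL, purpose = c("LOD", "LOQ"), loqK = 10) {
  distribution <- match.arg(distribution)
  purpose <- match.arg(purpose)
  if (purpose == "LOQ") {
    return(new("KFactorSpec", alpha = alpha, beta = beta,
               distribution = distribution,
               nBlanks = if (is.null(nBlanks)) integer() else as.integer(nBlanks),
               purpose = "LOQ", value = loqK))
  }
  value <- switch(distribution,
    normal = qnorm(1 - alpha) + qnorm(1 - beta),
    student_t = {
      if (is.null(nBlanks))
        stop("'nBlanks' is required for the Student-t k-factor")
      if (!isTRUE(all.equal(alpha, beta)))
        stop("the Student-t form is defined only for alpha == beta ",
             "(symmetric 2*t(1-alpha, N_b-1)); use distribution = 'normal' ",
             "for asymmetric error probabilities")
      2 * qt(1 - alpha, df = nBlanks - 1)
    })
  new("KFactorSpec", alpha = alpha, beta = beta, distribution = distribution,
      nBlanks = if (is.null(nBlanks)) integer() else as.integer(nBlanks),
      purpose = "LOD", value = value)
}

#' Symmetric error probability implied by a k-factor
#'
#' Inverse of the normal symmetric k-factor: for `k = z(1-p) + z(1-p)` the
#' implied alpha = beta is `1 - pnorm(k / 2)`. E.g. k = 3 implies about
#' 0.067 (~0.07) for both error types.
#'
#' @param k detection multiplier.
#' @return Error probability shared by alpha and beta.
#' @export
errorProbability <- function(k) {
  stopifnot(k > 0)
  1 - pnorm(k / 2)
}
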