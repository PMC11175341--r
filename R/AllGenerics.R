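#' @import methods
#' @importFrom stats coef cor fitted lm median predict prcomp pnorm qnorm qt
#'   quantile rnorm sd setNames var
#' @importFrom utils read.csv write.csv write.table head tail
NULL

#' Limit value of a detection- or quantification-limit estimate
#'
#' @param x A [LimitEstimate-class] object.
#' @return Numeric limit in ppm (`NA` when the method returned the
#'   not-detected sentinel).
#' @export
setGeneric("limitValue", function(x) standardGeneric("limitValue"))

#' Validity flag of a limit estimate
#'
#' @param x A [LimitEstimate-class] object.
#' @return `TRUE` when the estimate is usable; `FALSE` for degenerate,
#'   negative or out-of-range results (see `reason(x)`).
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' Reason attached to an invalid limit estimate
#' @param x A [LimitEstimate-class] object.
#' @return Character string ("" when valid).
#' @export
setGeneric("reason", function(x) standardGeneric("reason"))

#' Method label of a limit estimate
#' @param x A [LimitEstimate-class] object.
#' @return Character, e.g. `"PCA_II"` or `"PLSR(2)"`.
#' @export
setGeneric("methodLabel", function(x) standardGeneric("methodLabel"))

#' Calibration leverage term
#'
#' The design-dependent uncertainty term `h0 = 1/n + cbar^2 / sum((c_i -
#' cbar)^2)` of a univariate calibration: large for few, closely spaced or
#' off-centre concentration levels.
#'
#' @param x A [CalibrationCurve-class] object.
#' @return Numeric leverage, always `>= 1/n`.
#' @export
setGeneric("leverage", function(x) standardGeneric("leverage"))
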