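#' @include AllClasses.R
NULL

#' Extract methylated (unconverted C) read counts
#'
#' @param x a [MethCountSet-class] object.
#' @return An integer matrix, sites by experiments.
#' @export
setGeneric("methReads", function(x) standardGeneric("methReads"))

#' Extract total read coverage
#'
#' @param x a [MethCountSet-class] object.
#' @return An integer matrix, sites by experiments.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' Experiment types present in an object
#'
#' @param x a [MethCountSet-class] object.
#' @return Character vector, a subset of `c("BS", "OXBS", "TAB")`.
#' @export
setGeneric("experimentTypes", function(x) standardGeneric("experimentTypes"))

#' Joint estimation of 5-mC and 5-hmC levels for every site
#'
#' @param object a [MethCountSet-class] object.
#' @param ... further arguments passed to methods.
#' @return The object with per-site estimates attached (see the
#'   `MethCountSet` method).
#' @export
setGeneric("estimateLevels", function(object, ...)
  standardGeneric("estimateLevels"))

#' Retrieve per-site level estimates
#'
#' @param x a [MethCountSet-class] object on which [estimateLevels()] has
#'   been run.
#' @return A [MethLevelResults-class] `DataFrame`.
#' @export
setGeneric("levelResults", function(x) standardGeneric("levelResults"))
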