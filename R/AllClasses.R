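#' Recognised experiment types
#'
#' The three sequencing protocols the estimator understands, and the level
#' each one reads out as its binomial success probability (the "implied
#' level"): BS-seq reads p_m + p_h (bisulfite does not distinguish 5-mC from
#' 5-hmC), oxBS-seq reads p_m, and TAB-seq reads p_h.
#'
#' @format Character vector of length 3: `c("BS", "OXBS", "TAB")`.
#' @export
EXPERIMENT_TYPES <- c("BS", "OXBS", "TAB")

#' Container for per-site methylation counts from multiple experiments
#'
#' `MethCountSet` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] with two assays:
#' `methReads` (unconverted, i.e. C, read counts) and `totalReads`
#' (coverage), both sites-by-experiments.  Columns are experiment types
#' (`"BS"`, `"OXBS"`, `"TAB"`), at most one column per type; rows are
#' cytosine sites with their genomic coordinates in `rowRanges`.  A
#' zero-coverage cell means the experiment does not cover that site.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [MethCountSet()] for the constructor, [estimateLevels()],
#'   [readMethCounts()], [joinTracks()].
#' @export
setClass("MethCountSet",
         contains = "RangedSummarizedExperiment")

setValidity("MethCountSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("methReads", "totalReads") %in% an))
    return("assays 'methReads' and 'totalReads' are required")
  m <- SummarizedExperiment::assay(object, "methReads")
  n <- SummarizedExperiment::assay(object, "totalReads")
  cn <- colnames(object)
  if (is.null(cn) || !all(cn %in% EXPERIMENT_TYPES))
    return("column names must be experiment types: BS, OXBS, TAB")
  if (anyDuplicated(cn))
    return("at most one column per experiment type")
  if (any(m < 0) || any(n < 0))
    return("read counts must be non-negative")
  if (any(m > n))
    return("methReads cannot exceed totalReads")
  if (any(m != round(m)) || any(n != round(n)))
    return("read counts must be integers")
  TRUE
})

#' Per-site estimation results
#'
#' A `DataFrame` subclass holding, for each site, the estimated level
#' triple (`p_m`, `p_h`, `p_u`), the method that produced it
#' (`"FREQUENCY"` when the plug-in frequency solution already lies in the
#' probability simplex, `"EM"` otherwise), the number of EM iterations,
#' a convergence flag, the overshoot flag of the raw frequency solution
#' and the count of confidence-interval conflicts.
#'
#' @export
setClass("MethLevelResults", contains = "DFrame")

#' Maximum-likelihood level estimate for a single site
#'
#' The probability triple for one CpG site: `pM` (5-mC level), `pH`
#' (5-hmC level) and `pU` (unmethylated level), which are non-negative
#' and sum to one.  Diagnostics record how the estimate was obtained.
#'
#' @slot pM,pH,pU numeric scalars, the level triple on the simplex.
#' @slot method `"FREQUENCY"` if the frequency solution was already
#'   consistent (it is then the MLE), `"EM"` if expectation-maximization
#'   was required.
#' @slot iterations integer, EM iterations performed (0 for FREQUENCY).
#' @slot converged logical, `FALSE` only when EM hit its iteration cap.
#' @slot nConflicts integer, confidence-interval conflicts counted by
#'   [flagConflicts()] (`NA` until flagging is performed).
#' @seealso [emEstimate()], [frequencyEstimate()], [flagConflicts()]
#' @export
setClass("LevelEstimate",
         representation(pM = "numeric", pH = "numeric", pU = "numeric",
                        method = "character", iterations = "integer",
                        converged = "logical", nConflicts = "integer"))

setValidity("LevelEstimate", function(object) {
  p <- c(object@pM, object@pH, object@pU)
  if (length(p) != 3L || anyNA(p))
    return("pM, pH, pU must be numeric scalars")
  if (any(p < -1e-9))
    return("levels must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    return("levels must sum to 1")
  if (!object@method %in% c("FREQUENCY", "EM"))
    return("method must be FREQUENCY or EM")
  TRUE
})
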