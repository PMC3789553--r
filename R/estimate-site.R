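#' Plug-in frequency solution for one site
#'
#' Solves for the level triple (p_m, p_h, p_u) from the observed
#' unconverted-read frequencies of the supplied experiments, using the
#' implied-level map (BS reads p_m + p_h, oxBS reads p_m, TAB reads p_h).
#' With exactly two covered experiments the system is exactly determined,
#' e.g. for BS + TAB: `pH = f_TAB`, `pM = f_BS - f_TAB`.  With all three,
#' a coverage-weighted least-squares combination is used.  The returned
#' triple is *raw*: it can leave the probability simplex (negative p_m
#' from BS + TAB, or p_m + p_h > 1 from TAB + oxBS), which the
#' `overshoot` flag records.  When `overshoot` is `FALSE` the triple is
#' also the maximum-likelihood estimate.
#'
#' @param bs,oxbs,tab per-experiment read counts, each `c(C_reads,
#'   T_reads)` (unconverted, converted) or `NULL` if the experiment is
#'   absent.  A supplied experiment with zero total coverage is treated
#'   as absent.
#' @return A list with components `pM`, `pH`, `pU` (raw solution, may be
#'   outside `[0, 1]`), `overshoot` (logical) and `frequencies` (named
#'   vector of observed per-experiment frequencies, `NA` when absent).
#' @examples
#' frequencyEstimate(bs = c(6, 4), tab = c(2, 8))   # consistent: (0.4, 0.2, 0.4)
#' frequencyEstimate(bs = c(3, 7), tab = c(5, 5))   # overshoot: raw pM = -0.2
#' @export
frequencyEstimate <- function(bs = NULL, oxbs = NULL, tab = NULL) {
  m <- .obsMatrix(bs, oxbs, tab)
  fr <- .freqCore(m)
  if (fr$nCovered == 0L)
    stop("no experiment has positive coverage", call. = FALSE)
  if (fr$nCovered < 2L)
    stop("a single experiment cannot identify the (p_m, p_h) split; ",
         "at least two covered experiments are required", call. = FALSE)
  list(pM = fr$pM, pH = fr$pH, pU = 1 - fr$pM - fr$pH,
       overshoot = fr$overshoot,
       frequencies = c(BS = unname(fr$fBS), OXBS = unname(fr$fOXBS),
                       TAB = unname(fr$fTAB)))
}

#' Binomial log-likelihood of a level pair for one site
#'
#' Sum over the covered experiments of the binomial log pmf of the
#' observed unconverted-read count, with success probability equal to the
#' experiment's implied level (BS: p_m + p_h; oxBS: p_m; TAB: p_h).  The
#' full pmf including binomial coefficients is used, so values agree with
#' [stats::dbinom()].  Returns `-Inf` when an experiment observed
#' unconverted reads at implied level 0, or converted reads at implied
#' level 1.
#'
#' @param pM,pH candidate 5-mC and 5-hmC levels; must satisfy `pM >= 0`,
#'   `pH >= 0`, `pM + pH <= 1`.
#' @inheritParams frequencyEstimate
#' @return A numeric scalar (possibly `-Inf`).
#' @examples
#' logLikelihood(0.4, 0.2, bs = c(6, 4), tab = c(2, 8))
#' logLikelihood(0.5, 0, tab = c(1, 9), bs = c(5, 5))  # -Inf
#' @export
logLikelihood <- function(pM, pH, bs = NULL, oxbs = NULL, tab = NULL) {
  if (!is.numeric(pM) || !is.numeric(pH) || length(pM) != 1L ||
      length(pH) != 1L || anyNA(c(pM, pH)))
    stop("'pM' and 'pH' must be numeric scalars", call. = FALSE)
  if (pM < 0 || pH < 0 || pM + pH > 1 + 1e-12)
    stop("(pM, pH) must lie in the probability simplex", call. = FALSE)
  m <- .obsMatrix(bs, oxbs, tab)
  .loglikCore(m, pM, pH)
}

#' Constrained maximum-likelihood estimate for one site
#'
#' Maximum-likelihood estimate of the level triple (p_m, p_h, p_u) on the
#' probability simplex, combining read counts from two or three
#' experiment types.  With two experiments, when the plug-in frequency
#' solution already lies in the simplex it is the MLE and is returned
#' directly (`method = "FREQUENCY"`, zero iterations).  At overshoot
#' sites, and at every three-experiment site (where the over-determined
#' frequency combination is only an initializer, not the MLE), the
#' estimate is found by expectation-maximization over
#' latent read classes: the E-step splits each ambiguous read class
#' (BS C reads between 5-mC and 5-hmC; TAB T reads between 5-mC and
#' unmethylated; oxBS T reads between 5-hmC and unmethylated) in
#' proportion to the current levels, and the M-step is the multinomial
#' complete-data MLE.  The observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' @inheritParams frequencyEstimate
#' @param tol convergence tolerance: stop when the largest absolute
#'   parameter change in one iteration falls below `tol`.
#' @param maxIter iteration cap; if reached, the current estimate is
#'   returned with `converged = FALSE`.
#' @param keepTrace logical; if `TRUE`, attach the per-iteration
#'   observed-data log-likelihood trace as attribute `"logLikTrace"`.
#' @return A [LevelEstimate-class] object.
#' @examples
#' emEstimate(bs = c(6, 4), tab = c(2, 8))   # consistent site, frequency MLE
#' emEstimate(bs = c(3, 7), tab = c(5, 5))   # boundary MLE (0, 0.4, 0.6)
#' @export
emEstimate <- function(bs = NULL, oxbs = NULL, tab = NULL,
                       tol = 1e-10, maxIter = 500L, keepTrace = FALSE) {
  if (!is.numeric(tol) || tol <= 0)
    stop("'tol' must be positive", call. = FALSE)
  if (maxIter < 1L)
    stop("'maxIter' must be at least 1", call. = FALSE)
  m <- .obsMatrix(bs, oxbs, tab)
  fit <- .emCore(m, tol = tol, maxIter = as.integer(maxIter),
                 keepTrace = keepTrace)
  if (fit$nCovered == 0L)
    stop("no experiment has positive coverage", call. = FALSE)
  if (fit$nCovered < 2L)
    stop("a single experiment cannot identify the (p_m, p_h) split; ",
         "at least two covered experiments are required", call. = FALSE)
  est <- new("LevelEstimate", pM = fit$pM, pH = fit$pH, pU = fit$pU,
             method = fit$method, iterations = fit$iterations,
             converged = fit$converged, nConflicts = NA_integer_)
  if (keepTrace)
    attr(est, "logLikTrace") <- fit$trace[[1L]]
  est
}

#' Exhaustive grid search for the constrained MLE (test oracle)
#'
#' Evaluates [logLikelihood()] on the lattice `{(i*step, j*step): i, j >=
#' 0, (i + j)*step <= 1}` and returns the arg-max, breaking ties by
#' smallest `pM`, then smallest `pH`.  Intended as an independent check
#' of [emEstimate()]; it is never called by the estimator itself.
#'
#' @inheritParams frequencyEstimate
#' @param step lattice spacing, in `(0, 0.01]`.
#' @return A list with `pM`, `pH` and `logLik` at the arg-max.
#' @export
gridOracle <- function(bs = NULL, oxbs = NULL, tab = NULL, step = 1e-3) {
  if (!is.numeric(step) || step <= 0 || step > 0.01)
    stop("'step' must be in (0, 0.01]", call. = FALSE)
  m <- .obsMatrix(bs, oxbs, tab)
  lat <- .gridLattice(step)
  ll <- .latticeLoglik(m, lat)
  i <- which.max(ll)
  list(pM = lat$pM[i], pH = lat$pH[i], logLik = ll[i])
}

# Lattice with pM ascending, pH ascending within pM, so which.max's
# first-maximum rule implements the documented tie-break.  Cached because
# oracle checks sweep many sites at the same step.
.latticeEnv <- new.env(parent = emptyenv())

.gridLattice <- function(step) {
  key <- sprintf("%.17g", step)
  if (!is.null(.latticeEnv[[key]])) return(.latticeEnv[[key]])
  k <- floor(1 / step + 1e-9)
  i <- rep.int(0:k, (k:0) + 1L)
  j <- sequence((k:0) + 1L) - 1L
  pm <- i * step
  ph <- j * step
  ps <- (i + j) * step
  lat <- list(pM = pm, pH = ph,
              logPm = log(pm), log1mPm = log1p(-pmin(pm, 1)),
              logPh = log(ph), log1mPh = log1p(-pmin(ph, 1)),
              logPs = log(ps), log1mPs = log1p(-pmin(ps, 1)))
  .latticeEnv[[key]] <- lat
  lat
}

.latticeLoglik <- function(m, lat) {
  ll <- rep.int(lchoose(m[1L] + m[2L], m[1L]) +
                  lchoose(m[3L] + m[4L], m[3L]) +
                  lchoose(m[5L] + m[6L], m[5L]),
                length(lat$pM))
  addTerm <- function(ll, count, logv) if (count > 0) ll + count * logv else ll
  ll <- addTerm(ll, m[1L], lat$logPs)
  ll <- addTerm(ll, m[2L], lat$log1mPs)
  ll <- addTerm(ll, m[3L], lat$logPm)
  ll <- addTerm(ll, m[4L], lat$log1mPm)
  ll <- addTerm(ll, m[5L], lat$logPh)
  ll <- addTerm(ll, m[6L], lat$log1mPh)
  ll
}

#' Flag confidence-interval conflicts for one site
#'
#' For each covered experiment, computes a two-sided Wilson score
#' interval at level `1 - alpha` around the observed unconverted-read
#' frequency and counts a conflict when the joint estimate's implied
#' level for that experiment (BS: p_m + p_h; oxBS: p_m; TAB: p_h) falls
#' outside the interval.  Sites with one or more conflicts are "strongly
#' inconsistent": the joint estimate cannot be reconciled with that
#' experiment's own data, which in excess may indicate systematic
#' (non-sampling) error.
#'
#' @param estimate a [LevelEstimate-class] or a numeric triple
#'   `c(pM, pH, pU)` on the simplex.
#' @inheritParams frequencyEstimate
#' @param alpha confidence level complement, in `(0, 1)`; smaller alpha
#'   gives wider intervals and never more conflicts.
#' @return If `estimate` is a `LevelEstimate`, the estimate with its
#'   `nConflicts` slot filled in; otherwise the integer conflict count
#'   (0 to 3).
#' @examples
#' est <- emEstimate(bs = c(0, 50), tab = c(50, 0))
#' nConflicts(flagConflicts(est, bs = c(0, 50), tab = c(50, 0)))
#' @export
flagConflicts <- function(estimate, bs = NULL, oxbs = NULL, tab = NULL,
                          alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (is(estimate, "LevelEstimate")) {
    p <- c(estimate@pM, estimate@pH, estimate@pU)
  } else {
    p <- as.numeric(estimate)
    if (length(p) != 3L || anyNA(p) || any(p < -1e-9) ||
        abs(sum(p) - 1) > 1e-9)
      stop("'estimate' must be a simplex triple c(pM, pH, pU)",
           call. = FALSE)
  }
  m <- .obsMatrix(bs, oxbs, tab)
  k <- .conflictCore(m, p[1L], p[2L], alpha = alpha)
  if (is(estimate, "LevelEstimate")) {
    estimate@nConflicts <- as.integer(k)
    estimate
  } else {
    as.integer(k)
  }
}

#' @describeIn LevelEstimate-class accessor for the level triple.
#' @param object,x a `LevelEstimate`.
#' @export
setMethod("show", "LevelEstimate", function(object) {
  cat(sprintf("LevelEstimate: pM = %.6f, pH = %.6f, pU = %.6f\n",
              object@pM, object@pH, object@pU))
  cat(sprintf("  method: %s (%d iteration%s%s)",
              object@method, object@iterations,
              if (object@iterations == 1L) "" else "s",
              if (isFALSE(object@converged)) ", NOT converged" else ""))
  if (!is.na(object@nConflicts))
    cat(sprintf("; CI conflicts: %d", object@nConflicts))
  cat("\n")
})

#' @rdname LevelEstimate-class
#' @export
levelTriple <- function(x) c(pM = x@pM, pH = x@pH, pU = x@pU)

#' @rdname LevelEstimate-class
#' @export
nConflicts <- function(x) x@nConflicts
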