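#' Simulate read counts for sites with known levels
#'
#' Draws per-experiment read counts from independent binomial
#' distributions: for each requested experiment the unconverted-read
#' count is `Binomial(coverage, implied level)` with the implied-level
#' map BS: p_m + p_h, oxBS: p_m, TAB: p_h.  Uses R's current RNG
#' stream; call [set.seed()] for reproducibility.
#'
#' @param pM,pH true 5-mC and 5-hmC levels; recycled to a common length
#'   (one site per element); must lie in the probability simplex.
#' @param coverage per-experiment read depth (scalar or per-site).
#' @param experiments character vector of experiment types to simulate.
#' @return A [MethCountSet-class] with one column per experiment.
#' @examples
#' set.seed(1)
#' sim <- simulateSiteCounts(0.3, 0.2, coverage = 50, n = 5)
#' levelResults(estimateLevels(sim))
#' @param n number of replicate sites per (pM, pH) value.
#' @export
simulateSiteCounts <- function(pM, pH, coverage,
                               experiments = c("BS", "TAB"), n = 1L) {
  if (any(pM < 0) || any(pH < 0) || any(pM + pH > 1))
    stop("(pM, pH) must lie in the probability simplex", call. = FALSE)
  if (any(coverage < 1))
    stop("'coverage' must be at least 1", call. = FALSE)
  experiments <- match.arg(experiments, EXPERIMENT_TYPES, several.ok = TRUE)
  len <- max(length(pM), length(pH), length(coverage)) * n
  pM <- rep_len(rep(pM, each = n), len)
  pH <- rep_len(rep(pH, each = n), len)
  coverage <- rep_len(rep(coverage, each = n), len)
  implied <- list(BS = pM + pH, OXBS = pM, TAB = pH)
  mr <- tr <- matrix(0L, len, length(experiments),
                     dimnames = list(NULL, experiments))
  for (ty in intersect(EXPERIMENT_TYPES, experiments)) {
    mr[, ty] <- stats::rbinom(len, coverage, pmin(implied[[ty]], 1))
    tr[, ty] <- as.integer(coverage)
  }
  out <- MethCountSet(mr, tr)
  SummarizedExperiment::rowData(out)$truePM <- pM
  SummarizedExperiment::rowData(out)$truePH <- pH
  out
}

.simGrid <- function(gridStep) {
  k <- floor(1 / gridStep + 1e-9)
  i <- rep.int(0:k, (k:0) + 1L)
  j <- sequence((k:0) + 1L) - 1L
  data.frame(pM = i * gridStep, pH = j * gridStep)
}

#' Simulation study of estimator error at overshoot sites
#'
#' Regenerates the binomial accuracy study comparing the joint
#' maximum-likelihood estimator with the naive frequency method.  For
#' every valid (p_m, p_h) combination on a grid and every coverage,
#' read counts are drawn from independent binomials for the requested
#' experiment pair, both estimators are applied, and errors of the
#' 5-hmC estimate are averaged over the replicates where the raw
#' frequency solution leaves the probability simplex (the overshoot
#' replicates, where the two methods differ).
#'
#' The frequency method's reported estimate at overshoot replicates is
#' the naive practice: the directly measured frequency is used as-is
#' (e.g. p_h from TAB-seq) and a negative subtraction result is clipped
#' to 0; levels from direct readouts are not rescaled.  The joint
#' estimator is the constrained MLE from [emEstimate()].
#'
#' @param gridStep spacing of the true-level grid (default 0.05).
#' @param coverages integer vector of per-experiment read depths.
#' @param replicates simulated sites per grid point and coverage.
#' @param experiments experiment pair (or triple) to simulate.
#' @param seed integer seed; the study is deterministic given it.
#'   Counts are drawn coverage-major, then grid-point-major, each grid
#'   point's replicate block drawn per experiment in the fixed order
#'   BS, OXBS, TAB.
#' @param tol,maxIter EM controls, as in [emEstimate()].
#' @return A `data.frame` with one row per (pM, pH, coverage):
#'   `nOvershoot`, `overshootProportion`, mean absolute and relative
#'   errors of the 5-hmC estimate at overshoot replicates for both
#'   methods (`meanAbsErrorFreq`, `meanAbsErrorMLE`, `meanRelErrorFreq`,
#'   `meanRelErrorMLE`; relative errors only where p_h > 0), and
#'   `errorReductionPct` = 100 * (1 - MLE error / frequency error),
#'   using the relative errors where p_h > 0 and absolute errors at
#'   p_h = 0.
#' @seealso [errorReductionAtOvershoot()], [writeStudyTable()]
#' @export
runOvershootStudy <- function(gridStep = 0.05, coverages = c(5L, 10L, 20L),
                              replicates = 10000L,
                              experiments = c("BS", "TAB"), seed = NULL,
                              tol = 1e-10, maxIter = 500L) {
  if (!is.numeric(gridStep) || gridStep <= 0 || gridStep > 1)
    stop("'gridStep' must be in (0, 1]", call. = FALSE)
  if (any(coverages < 1))
    stop("'coverages' must be positive integers", call. = FALSE)
  if (replicates < 1)
    stop("'replicates' must be at least 1", call. = FALSE)
  experiments <- match.arg(experiments, EXPERIMENT_TYPES, several.ok = TRUE)
  if (length(experiments) < 2L)
    stop("at least two experiment types are required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  grid <- .simGrid(gridStep)
  ng <- nrow(grid)
  out <- vector("list", length(coverages))
  for (ci in seq_along(coverages)) {
    cov <- as.integer(coverages[ci])
    # draw all counts for this coverage, grid-point-major
    m <- matrix(0, ng * replicates, 6L, dimnames = list(NULL, .OBS_COLS))
    implied <- cbind(BS = grid$pM + grid$pH, OXBS = grid$pM, TAB = grid$pH)
    for (g in seq_len(ng)) {
      rows <- ((g - 1L) * replicates + 1L):(g * replicates)
      for (ty in intersect(EXPERIMENT_TYPES, experiments)) {
        k <- match(ty, EXPERIMENT_TYPES)
        cr <- stats::rbinom(replicates, cov, min(implied[g, ty], 1))
        m[rows, 2L * k - 1L] <- cr
        m[rows, 2L * k] <- cov - cr
      }
    }
    fit <- .emCore(m, tol = tol, maxIter = as.integer(maxIter))
    truePH <- rep(grid$pH, each = replicates)
    # naive frequency estimate of p_h at every replicate
    fr <- fit$freq
    if ("TAB" %in% experiments) {
      phFreq <- fr$fTAB                       # direct readout, as-is
    } else {
      phFreq <- pmax(fr$fBS - fr$fOXBS, 0)    # subtraction, clipped at 0
    }
    os <- fit$overshoot
    gidx <- rep(seq_len(ng), each = replicates)
    absF <- abs(phFreq - truePH)
    absM <- abs(fit$pH - truePH)
    sumBy <- function(v, w) {
      x <- numeric(ng)
      s <- tapply(v[w], gidx[w], sum)
      x[as.integer(names(s))] <- s
      x
    }
    nOs <- sumBy(rep(1, length(os)), os)
    mAbsF <- ifelse(nOs > 0, sumBy(absF, os) / nOs, NA_real_)
    mAbsM <- ifelse(nOs > 0, sumBy(absM, os) / nOs, NA_real_)
    mRelF <- ifelse(grid$pH > 0, mAbsF / grid$pH, NA_real_)
    mRelM <- ifelse(grid$pH > 0, mAbsM / grid$pH, NA_real_)
    errF <- ifelse(grid$pH > 0, mRelF, mAbsF)
    errM <- ifelse(grid$pH > 0, mRelM, mAbsM)
    red <- ifelse(!is.na(errF) & errF > 0, 100 * (1 - errM / errF),
                  NA_real_)
    out[[ci]] <- data.frame(
      pM = grid$pM, pH = grid$pH, coverage = cov,
      nOvershoot = as.integer(nOs),
      overshootProportion = nOs / replicates,
      meanAbsErrorFreq = mAbsF, meanAbsErrorMLE = mAbsM,
      meanRelErrorFreq = mRelF, meanRelErrorMLE = mRelM,
      errorReductionPct = red)
  }
  res <- do.call(rbind, out)
  attr(res, "config") <- list(gridStep = gridStep, coverages = coverages,
                              replicates = replicates,
                              experiments = experiments, seed = seed,
                              rng = RNGkind()[1L])
  res
}

#' Largest error reduction achieved at a given coverage
#'
#' Scans a [runOvershootStudy()] table and returns the maximum over grid
#' points of the percent reduction in average 5-hmC estimation error at
#' overshoot replicates (relative error where p_h > 0, absolute error at
#' p_h = 0) achieved by the joint MLE over the frequency method.
#'
#' @param study a table from [runOvershootStudy()].
#' @param coverage which coverage to scan; must be present in the table.
#' @return Numeric scalar, a percentage.
#' @export
errorReductionAtOvershoot <- function(study, coverage) {
  rows <- study$coverage == coverage
  if (!any(rows))
    stop("coverage ", coverage, " not present in the study table",
         call. = FALSE)
  red <- study$errorReductionPct[rows]
  if (all(is.na(red)))
    return(NA_real_)
  max(red, na.rm = TRUE)
}

#' Write a study table as TSV
#'
#' Tab-delimited output with a `#` header echoing the configuration
#' (grid step, coverages, replicates, experiments, seed, RNG).
#'
#' @param study a table from [runOvershootStudy()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeStudyTable <- function(study, path) {
  cfg <- attr(study, "config")
  hdr <- sprintf(
    "# overshoot study: gridStep=%g coverages=%s replicates=%d experiments=%s seed=%s rng=%s",
    cfg$gridStep, paste(cfg$coverages, collapse = ","), cfg$replicates,
    paste(cfg$experiments, collapse = "+"),
    if (is.null(cfg$seed)) "NA" else cfg$seed, cfg$rng)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(study, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
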