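#' Construct a MethCountSet
#'
#' Builds the central count container either from count matrices or from
#' a joined track table (see [joinTracks()]).
#'
#' @param methReads integer matrix of unconverted (C) read counts, sites
#'   by experiments; column names must be experiment types (`"BS"`,
#'   `"OXBS"`, `"TAB"`).
#' @param totalReads integer matrix of read coverages, same shape.
#' @param rowRanges optional [GenomicRanges::GRanges] of site
#'   coordinates (1-based starts; the methcounts format on disk is
#'   0-based and converted on read/write).  Synthetic single-width
#'   ranges are generated when omitted.
#' @param context optional character vector of sequence contexts,
#'   recycled; stored in `rowData`.
#' @return A [MethCountSet-class] object.
#' @examples
#' mcs <- MethCountSet(methReads = cbind(BS = 6, TAB = 2),
#'                     totalReads = cbind(BS = 10, TAB = 10))
#' levelResults(estimateLevels(mcs))
#' @export
MethCountSet <- function(methReads, totalReads, rowRanges = NULL,
                         context = "CpG") {
  methReads <- as.matrix(methReads)
  totalReads <- as.matrix(totalReads)
  storage.mode(methReads) <- "integer"
  storage.mode(totalReads) <- "integer"
  n <- nrow(methReads)
  if (is.null(rowRanges)) {
    rowRanges <- GenomicRanges::GRanges(
      seqnames = rep("unplaced", n),
      ranges = IRanges::IRanges(start = seq_len(max(n, 1L))[seq_len(n)],
                                width = 1L),
      strand = rep("+", n))
  }
  rd <- S4Vectors::DataFrame(context = rep_len(context, n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(methReads = methReads, totalReads = totalReads),
    rowRanges = rowRanges,
    colData = S4Vectors::DataFrame(experiment = colnames(methReads),
                                   row.names = colnames(methReads)))
  SummarizedExperiment::rowData(se)$context <- rd$context
  methods::new("MethCountSet", se)
}

#' Build a MethCountSet from per-experiment track files
#'
#' Convenience wrapper: reads each supplied methcounts-style file,
#' joins them site-by-site and converts level/coverage to read counts
#' with [countsFromLevel()].
#'
#' @param bs,oxbs,tab paths to per-experiment track files; supply at
#'   least two.
#' @param strict passed to [joinTracks()].
#' @return A [MethCountSet-class].
#' @export
readMethCountSet <- function(bs = NULL, oxbs = NULL, tab = NULL,
                             strict = TRUE) {
  paths <- list(BS = bs, OXBS = oxbs, TAB = tab)
  paths <- paths[!vapply(paths, is.null, logical(1L))]
  if (length(paths) < 2L)
    stop("at least two of 'bs', 'oxbs', 'tab' are required", call. = FALSE)
  tracks <- lapply(paths, readMethCounts)
  joined <- joinTracks(tracks, strict = strict)
  types <- names(tracks)
  mr <- tr <- matrix(0L, nrow(joined), length(types),
                     dimnames = list(NULL, types))
  for (ty in types) {
    cts <- countsFromLevel(joined[[paste0("level.", ty)]],
                           joined[[paste0("coverage.", ty)]])
    mr[, ty] <- cts[, "cReads"]
    tr[, ty] <- as.integer(joined[[paste0("coverage.", ty)]])
  }
  rr <- GenomicRanges::GRanges(
    seqnames = joined$chrom,
    ranges = IRanges::IRanges(start = joined$position + 1L, width = 1L),
    strand = joined$strand)
  MethCountSet(mr, tr, rowRanges = rr, context = joined$context)
}

#' @rdname methReads
#' @export
setMethod("methReads", "MethCountSet", function(x)
  SummarizedExperiment::assay(x, "methReads"))

#' @rdname totalReads
#' @export
setMethod("totalReads", "MethCountSet", function(x)
  SummarizedExperiment::assay(x, "totalReads"))

#' @rdname experimentTypes
#' @export
setMethod("experimentTypes", "MethCountSet", function(x) colnames(x))

# sites x 6 observation matrix used by the estimation core
.obsFromSet <- function(x) {
  m <- matrix(0, nrow(x), 6L, dimnames = list(NULL, .OBS_COLS))
  mr <- methReads(x)
  tr <- totalReads(x)
  for (ty in intersect(EXPERIMENT_TYPES, colnames(x))) {
    k <- match(ty, EXPERIMENT_TYPES)
    m[, 2L * k - 1L] <- mr[, ty]
    m[, 2L * k] <- tr[, ty] - mr[, ty]
  }
  m
}

#' @describeIn estimateLevels Estimates the (p_m, p_h, p_u) triple at
#'   every site by constrained maximum likelihood (frequency solution
#'   when consistent, EM at overshoot sites), counts Wilson-interval
#'   conflicts at level `1 - alpha`, and stores the results in
#'   `rowData`.  Sites with fewer than two covered experiments are
#'   unidentified and reported as `NA` (with the directly measured
#'   margin retained where one exists: oxBS alone identifies p_m, TAB
#'   alone identifies p_h).
#'
#' @param alpha confidence level complement for conflict flagging.
#' @param tol,maxIter EM convergence controls, as in [emEstimate()].
#' @export
setMethod("estimateLevels", "MethCountSet",
          function(object, alpha = 0.05, tol = 1e-10, maxIter = 500L) {
  m <- .obsFromSet(object)
  fit <- .emCore(m, tol = tol, maxIter = as.integer(maxIter))
  conf <- rep(NA_integer_, nrow(m))
  ok <- which(fit$nCovered >= 2L)
  if (length(ok))
    conf[ok] <- .conflictCore(m[ok, , drop = FALSE],
                              fit$pM[ok], fit$pH[ok], alpha = alpha)
  # single-experiment sites: keep the directly measured margin
  pm <- fit$pM; ph <- fit$pH; pu <- fit$pU
  solo <- fit$nCovered == 1L
  if (any(solo)) {
    pm[solo & !is.na(fit$freq$fOXBS)] <-
      fit$freq$fOXBS[solo & !is.na(fit$freq$fOXBS)]
    ph[solo & !is.na(fit$freq$fTAB)] <-
      fit$freq$fTAB[solo & !is.na(fit$freq$fTAB)]
  }
  rd <- SummarizedExperiment::rowData(object)
  rd$pM <- pm
  rd$pH <- ph
  rd$pU <- pu
  rd$method <- fit$method
  rd$iterations <- fit$iterations
  rd$converged <- fit$converged
  rd$overshoot <- fit$overshoot
  rd$nConflicts <- conf
  SummarizedExperiment::rowData(object) <- rd
  S4Vectors::metadata(object)$estimateLevels <-
    list(alpha = alpha, tol = tol, maxIter = as.integer(maxIter))
  object
})

#' @rdname levelResults
#' @export
setMethod("levelResults", "MethCountSet", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (is.null(rd$pM))
    stop("no estimates present; run estimateLevels() first", call. = FALSE)
  cols <- c("context", "pM", "pH", "pU", "method", "iterations",
            "converged", "overshoot", "nConflicts")
  res <- rd[intersect(cols, colnames(rd))]
  S4Vectors::metadata(res) <- S4Vectors::metadata(x)$estimateLevels
  methods::new("MethLevelResults", res)
})

#' @export
setMethod("show", "MethCountSet", function(object) {
  cat(sprintf("MethCountSet: %d sites x %d experiments (%s)\n",
              nrow(object), ncol(object),
              paste(colnames(object), collapse = ", ")))
  cov <- totalReads(object)
  if (nrow(object))
    cat(sprintf("  mean coverage: %s\n",
                paste(sprintf("%s=%.1f", colnames(object), colMeans(cov)),
                      collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!is.null(rd$pM)) {
    est <- sum(!is.na(rd$pM))
    cat(sprintf("  estimates: %d/%d sites (%d by EM, %d conflicts flagged)\n",
                est, nrow(object),
                sum(rd$method == "EM", na.rm = TRUE),
                sum(rd$nConflicts > 0, na.rm = TRUE)))
  }
})

#' @export
setMethod("show", "MethLevelResults", function(object) {
  cat(sprintf("MethLevelResults with %d sites\n", nrow(object)))
  methods::callNextMethod()
})
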