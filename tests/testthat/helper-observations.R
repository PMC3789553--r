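# Shared generators and oracles for the test suite.  All randomness uses
# the caller's seed (tests set.seed() themselves).

# Random level triples on the simplex, with extra mass on edges and
# corners where overshoot (and boundary MLEs) concentrate.
randomTruth <- function(n) {
  u <- matrix(stats::rexp(3 * n), ncol = 3)
  p <- u / rowSums(u)
  edge <- stats::runif(n) < 0.3
  if (any(edge)) {
    k <- sample(3L, sum(edge), replace = TRUE)
    p[cbind(which(edge), k)] <- 0
    p[edge, ] <- p[edge, , drop = FALSE] / rowSums(p[edge, , drop = FALSE])
  }
  corner <- stats::runif(n) < 0.05
  if (any(corner)) {
    k <- sample(3L, sum(corner), replace = TRUE)
    p[corner, ] <- 0
    p[cbind(which(corner), k)] <- 1
  }
  colnames(p) <- c("pM", "pH", "pU")
  p
}

EXP_COMBOS <- list(c("BS", "TAB"), c("BS", "OXBS"), c("OXBS", "TAB"),
                   c("BS", "OXBS", "TAB"))

# n random sites: truth drawn from randomTruth, experiment combo drawn
# from EXP_COMBOS, per-experiment coverage uniform in [minCov, maxCov],
# counts binomial at the implied level.  Returns the 6-column count
# matrix (bsC bsT oxC oxT tabC tabT) plus the truth and combo index.
randomObsCounts <- function(n, minCov = 1L, maxCov = 200L) {
  p <- randomTruth(n)
  combo <- sample(length(EXP_COMBOS), n, replace = TRUE)
  m <- matrix(0, n, 6L,
              dimnames = list(NULL, c("bsC", "bsT", "oxC", "oxT",
                                      "tabC", "tabT")))
  implied <- cbind(BS = p[, 1L] + p[, 2L], OXBS = p[, 1L], TAB = p[, 2L])
  for (k in 1:3) {
    ty <- c("BS", "OXBS", "TAB")[k]
    present <- vapply(EXP_COMBOS[combo], function(x) ty %in% x, logical(1))
    cov <- ifelse(present,
                  sample.int(maxCov - minCov + 1L, n, replace = TRUE) +
                    minCov - 1L, 0L)
    cr <- stats::rbinom(n, cov, pmin(implied[, ty], 1))
    m[, 2L * k - 1L] <- cr
    m[, 2L * k] <- cov - cr
  }
  list(counts = m, truth = p, combo = combo)
}

# Per-site argument list for the scalar API, dropping zero-coverage
# experiments.
siteArgs <- function(mrow) {
  a <- list()
  if (mrow[1L] + mrow[2L] > 0) a$bs <- c(mrow[1L], mrow[2L])
  if (mrow[3L] + mrow[4L] > 0) a$oxbs <- c(mrow[3L], mrow[4L])
  if (mrow[5L] + mrow[6L] > 0) a$tab <- c(mrow[5L], mrow[6L])
  a
}

# MethCountSet from a 6-column count matrix (zero-coverage = absent).
mcsFromCounts <- function(m) {
  MethCountSet(
    methReads = cbind(BS = m[, 1L], OXBS = m[, 3L], TAB = m[, 5L]),
    totalReads = cbind(BS = m[, 1L] + m[, 2L], OXBS = m[, 3L] + m[, 4L],
                       TAB = m[, 5L] + m[, 6L]))
}

# Write a methcounts-style track file.
writeTrack <- function(df, path = tempfile(fileext = ".meth")) {
  lines <- with(df, paste(chrom, position, strand, context,
                          format(level, digits = 10), coverage, sep = "\t"))
  writeLines(lines, path)
  path
}

trackFrame <- function(chrom, position, strand, context, level, coverage) {
  data.frame(chrom = chrom, position = position, strand = strand,
             context = context, level = level, coverage = coverage,
             stringsAsFactors = FALSE)
}

# Exact overshoot probability for a BS+TAB pair at one (pM, pH, cov):
# P(f_TAB > f_BS), by enumerating the joint binomial pmf.
exactOvershootBsTab <- function(pM, pH, cov) {
  t <- 0:cov
  h <- 0:cov
  pt <- stats::dbinom(t, cov, pM + pH)
  ph_ <- stats::dbinom(h, cov, pH)
  sum(outer(pt, ph_) * outer(t, h, FUN = "<"))
}
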