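test_that("degenerate level combinations give deterministic counts", {
  set.seed(59)
  sim <- simulateSiteCounts(1, 0, coverage = 10, n = 20)
  expect_true(all(methReads(sim)[, "BS"] == 10L))
  expect_true(all(methReads(sim)[, "TAB"] == 0L))
  sim <- simulateSiteCounts(0, 0, coverage = 10, n = 20,
                            experiments = c("BS", "OXBS", "TAB"))
  expect_true(all(methReads(sim) == 0L))
  expect_error(simulateSiteCounts(0.7, 0.6, coverage = 10), "simplex")
})

test_that("empirical frequencies approach the implied levels", {
  set.seed(61)
  sim <- simulateSiteCounts(0.3, 0.2, coverage = 10000, n = 1,
                            experiments = c("BS", "OXBS", "TAB"))
  f <- methReads(sim)[1, ] / 10000
  expect_lt(abs(f[["BS"]] - 0.5), 0.02)
  expect_lt(abs(f[["OXBS"]] - 0.3), 0.02)
  expect_lt(abs(f[["TAB"]] - 0.2), 0.02)
})

test_that("the study is deterministic given its seed", {
  a <- runOvershootStudy(gridStep = 0.5, coverages = 10L,
                         replicates = 100L, seed = 1)
  b <- runOvershootStudy(gridStep = 0.5, coverages = 10L,
                         replicates = 100L, seed = 1)
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
})

test_that("overshoot proportion matches exhaustive enumeration", {
  # P(overshoot) for BS+TAB is P(f_TAB > f_BS); enumerate the joint
  # binomial pmf and require Monte-Carlo agreement within 3 SEs
  st <- runOvershootStudy(gridStep = 0.25, coverages = 10L,
                          replicates = 4000L, seed = 71)
  for (r in seq_len(nrow(st))) {
    pexact <- exactOvershootBsTab(st$pM[r], st$pH[r], 10L)
    se <- sqrt(pexact * (1 - pexact) / 4000)
    expect_lt(abs(st$overshootProportion[r] - pexact), 3 * se + 1e-12)
  }
})

test_that("overshoot never occurs at degenerate implied levels", {
  st <- runOvershootStudy(gridStep = 1, coverages = 5L,
                          replicates = 200L, seed = 73)
  # grid = the three simplex corners; all binomials are degenerate
  expect_true(all(st$overshootProportion == 0))
})

test_that("at overshoot outcomes the EM likelihood beats the clipped frequency point", {
  # enumerate every (t, h) outcome at coverage 6 for a BS+TAB pair
  for (t in 0:6) for (h in 0:6) {
    if (h <= t) next  # not overshoot
    bs <- c(t, 6 - t); tab <- c(h, 6 - h)
    est <- emEstimate(bs = bs, tab = tab)
    llEM <- logLikelihood(est@pM, est@pH, bs = bs, tab = tab)
    llFreq <- logLikelihood(0, h / 6, bs = bs, tab = tab)
    expect_gt(llEM, llFreq - 1e-12)
    if (t > 0) expect_gt(llEM, llFreq)
  }
})

test_that("error reduction lookup validates its coverage", {
  st <- runOvershootStudy(gridStep = 0.5, coverages = 10L,
                          replicates = 200L, seed = 79)
  expect_error(errorReductionAtOvershoot(st, 99L), "not present")
  expect_true(is.numeric(errorReductionAtOvershoot(st, 10L)))
})

test_that("study tables serialize with a config header", {
  st <- runOvershootStudy(gridStep = 0.5, coverages = 5L,
                          replicates = 50L, seed = 83)
  p <- tempfile()
  writeStudyTable(st, p)
  lines <- readLines(p)
  expect_match(lines[1], "gridStep=0.5.*replicates=50.*seed=83")
  d <- read.delim(p, comment.char = "#")
  expect_identical(nrow(d), nrow(st))
})
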