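test_that("overshoot sites converge to the known boundary MLEs", {
  # BS+TAB overshoot: at the boundary p_m = 0 both experiments measure
  # p_h, so the MLE pools counts: p_h = (3 + 5) / 20
  est <- emEstimate(bs = c(3, 7), tab = c(5, 5))
  expect_equal(levelTriple(est), c(pM = 0, pH = 0.4, pU = 0.6),
               tolerance = 1e-8)
  expect_identical(est@method, "EM")
  expect_true(est@converged)

  # TAB+OXBS overshoot: on the boundary p_u = 0 the likelihood is that
  # of a single binomial in p_h with pooled counts: p_h = 13 / 20
  est <- emEstimate(tab = c(8, 2), oxbs = c(5, 5))
  expect_equal(levelTriple(est), c(pM = 0.35, pH = 0.65, pU = 0),
               tolerance = 1e-8)

  # BS+OXBS overshoot (negative p_h): mirror of the first case
  est <- emEstimate(bs = c(3, 7), oxbs = c(5, 5))
  expect_equal(levelTriple(est), c(pM = 0.4, pH = 0, pU = 0.6),
               tolerance = 1e-8)
})

test_that("consistent two-experiment sites return the frequency solution untouched", {
  est <- emEstimate(bs = c(6, 4), tab = c(2, 8))
  expect_identical(est@method, "FREQUENCY")
  expect_identical(est@iterations, 0L)
  expect_equal(levelTriple(est), c(pM = 0.4, pH = 0.2, pU = 0.4))

  set.seed(7)
  for (i in 1:300) {
    obs <- randomObsCounts(1, minCov = 1L, maxCov = 100L)
    a <- siteArgs(obs$counts[1, ])
    fe <- do.call(frequencyEstimate, a)
    if (!fe$overshoot && length(a) == 2L) {
      est <- do.call(emEstimate, a)
      expect_identical(est@method, "FREQUENCY")
      expect_equal(unname(levelTriple(est)), c(fe$pM, fe$pH, fe$pU),
                   tolerance = 1e-12)
    }
  }
})

test_that("three-experiment sites are decided by the likelihood", {
  # exactly consistent frequencies solve all three binomials at once:
  # the joint MLE is that common solution
  est <- emEstimate(bs = c(6, 4), oxbs = c(4, 6), tab = c(2, 8))
  expect_equal(unname(levelTriple(est)), c(0.4, 0.2, 0.4),
               tolerance = 1e-6)

  # otherwise the MLE must weakly beat the least-squares frequency
  # combination in likelihood
  set.seed(9)
  for (i in 1:100) {
    cov <- sample(1:80, 3, replace = TRUE)
    cts <- rbinom(3, cov, runif(3))
    a <- list(bs = c(cts[1], cov[1] - cts[1]),
              oxbs = c(cts[2], cov[2] - cts[2]),
              tab = c(cts[3], cov[3] - cts[3]))
    fe <- do.call(frequencyEstimate, a)
    if (fe$overshoot) next
    est <- do.call(emEstimate, a)
    llEM <- do.call(logLikelihood, c(list(est@pM, est@pH), a))
    llLS <- do.call(logLikelihood,
                    c(list(min(max(fe$pM, 0), 1), min(max(fe$pH, 0), 1)), a))
    expect_gte(llEM, llLS - 1e-10)
  }
})

test_that("estimates always lie on the probability simplex", {
  set.seed(11)
  obs <- randomObsCounts(2000, minCov = 1L, maxCov = 200L)
  res <- levelResults(estimateLevels(mcsFromCounts(obs$counts)))
  expect_false(anyNA(res$pM))
  expect_true(all(res$pM >= 0 & res$pH >= 0 & res$pU >= 0))
  expect_true(all(abs(res$pM + res$pH + res$pU - 1) <= 1e-9))
})

test_that("observed-data log-likelihood never decreases across iterations", {
  set.seed(13)
  checked <- 0L
  while (checked < 200L) {
    obs <- randomObsCounts(1, minCov = 1L, maxCov = 200L)
    a <- siteArgs(obs$counts[1, ])
    if (!do.call(frequencyEstimate, a)$overshoot) next
    est <- do.call(emEstimate, c(a, keepTrace = TRUE))
    trace <- attr(est, "logLikTrace")
    expect_true(all(diff(trace) >= -1e-12))
    checked <- checked + 1L
  }
})

test_that("a zero-coverage third experiment does not change the estimate", {
  set.seed(17)
  for (i in 1:100) {
    cov <- sample(1:80, 2)
    bs <- c(rbinom(1, cov[1], runif(1)), 0); bs[2] <- cov[1] - bs[1]
    tab <- c(rbinom(1, cov[2], runif(1)), 0); tab[2] <- cov[2] - tab[1]
    e2 <- emEstimate(bs = bs, tab = tab)
    e3 <- emEstimate(bs = bs, tab = tab, oxbs = c(0, 0))
    expect_equal(levelTriple(e3), levelTriple(e2), tolerance = 1e-12)
  }
})

test_that("BS+TAB and BS+OXBS estimates are symmetric in pM and pH", {
  set.seed(19)
  for (i in 1:150) {
    cov <- sample(1:60, 2)
    bs <- c(rbinom(1, cov[1], runif(1)), 0); bs[2] <- cov[1] - bs[1]
    other <- c(rbinom(1, cov[2], runif(1)), 0); other[2] <- cov[2] - other[1]
    a <- levelTriple(emEstimate(bs = bs, tab = other))
    b <- levelTriple(emEstimate(bs = bs, oxbs = other))
    # boundary components sit within the EM stopping tolerance of zero,
    # so compare absolutely at that scale
    expect_true(all(abs(a[c("pH", "pM", "pU")] - b) < 1e-8))
  }
})

test_that("the iteration cap is honoured and reported", {
  est <- emEstimate(bs = c(3, 7), tab = c(5, 5), maxIter = 2L)
  expect_false(est@converged)
  expect_identical(est@iterations, 2L)
  expect_error(emEstimate(bs = c(3, 7), tab = c(5, 5), maxIter = 0L),
               "maxIter")
  expect_error(emEstimate(bs = c(3, 7), tab = c(5, 5), tol = 0), "tol")
})

test_that("high-coverage estimates recover the truth", {
  set.seed(23)
  truths <- rbind(c(0.3, 0.2), c(0.05, 0.05), c(0, 0.4), c(0.7, 0.25))
  for (r in seq_len(nrow(truths))) {
    sim <- simulateSiteCounts(truths[r, 1], truths[r, 2],
                              coverage = 5000, n = 50)
    res <- levelResults(estimateLevels(sim))
    expect_equal(mean(res$pM), truths[r, 1], tolerance = 0.01)
    expect_equal(mean(res$pH), truths[r, 2], tolerance = 0.01)
  }
})
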