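test_that("pairwise frequency solutions follow the implied-level map", {
  # BS + TAB: p_h from TAB directly, p_m by subtraction
  fe <- frequencyEstimate(bs = c(6, 4), tab = c(2, 8))
  expect_equal(c(fe$pM, fe$pH, fe$pU), c(0.4, 0.2, 0.4))
  expect_false(fe$overshoot)

  # BS + OXBS: p_m from oxBS directly, p_h by subtraction
  fe <- frequencyEstimate(bs = c(6, 4), oxbs = c(2, 8))
  expect_equal(c(fe$pM, fe$pH, fe$pU), c(0.2, 0.4, 0.4))
  expect_false(fe$overshoot)

  # TAB + OXBS: both measured directly, p_u by subtraction
  fe <- frequencyEstimate(tab = c(2, 8), oxbs = c(4, 6))
  expect_equal(c(fe$pM, fe$pH, fe$pU), c(0.4, 0.2, 0.4))
  expect_false(fe$overshoot)
})

test_that("both overshoot modes are detected on the raw solution", {
  # negative 5-mC from BS + TAB
  fe <- frequencyEstimate(bs = c(3, 7), tab = c(5, 5))
  expect_equal(fe$pM, -0.2)
  expect_true(fe$overshoot)

  # 5-mC + 5-hmC above 1 from TAB + OXBS
  fe <- frequencyEstimate(tab = c(8, 2), oxbs = c(5, 5))
  expect_equal(fe$pM + fe$pH, 1.3)
  expect_true(fe$overshoot)

  # a frequency solution exactly on the simplex boundary is consistent
  fe <- frequencyEstimate(bs = c(5, 5), tab = c(5, 5))
  expect_equal(fe$pM, 0)
  expect_false(fe$overshoot)
})

test_that("three-experiment solution is coverage-weighted least squares", {
  # equal coverages, consistent frequencies: exact solution recovered
  fe <- frequencyEstimate(bs = c(6, 4), oxbs = c(4, 6), tab = c(2, 8))
  expect_equal(c(fe$pM, fe$pH), c(0.4, 0.2))

  # verified against an independent lm() fit with coverage weights
  bs <- c(7, 3); oxbs <- c(3, 9); tab <- c(2, 8)
  fe <- frequencyEstimate(bs = bs, oxbs = oxbs, tab = tab)
  f <- c(0.7, 3 / 12, 0.2)
  A <- rbind(c(1, 1), c(1, 0), c(0, 1))
  w <- c(10, 12, 10)
  ref <- stats::lm.wfit(A, f, w)$coefficients
  expect_equal(c(fe$pM, fe$pH), unname(ref))

  # a zero-coverage third experiment reduces to the pair solution
  fe3 <- frequencyEstimate(bs = c(6, 4), tab = c(2, 8), oxbs = c(0, 0))
  fe2 <- frequencyEstimate(bs = c(6, 4), tab = c(2, 8))
  expect_equal(fe3[c("pM", "pH", "pU")], fe2[c("pM", "pH", "pU")])
})

test_that("degenerate inputs are refused with informative errors", {
  expect_error(frequencyEstimate(bs = c(0, 0), tab = c(0, 0)),
               "no experiment")
  expect_error(frequencyEstimate(bs = c(6, 4)), "at least two")
  expect_error(frequencyEstimate(bs = c(6, 4), tab = c(0, 0)),
               "at least two")
  expect_error(frequencyEstimate(bs = c(-1, 4), tab = c(2, 8)),
               "non-negative")
  expect_error(frequencyEstimate(bs = c(1.5, 4), tab = c(2, 8)),
               "integer")
})

test_that("relabelling BS+TAB as BS+OXBS swaps the roles of pM and pH", {
  set.seed(101)
  for (i in 1:200) {
    cov <- sample(1:60, 2)
    bs <- c(rbinom(1, cov[1], runif(1)), 0); bs[2] <- cov[1] - bs[1]
    other <- c(rbinom(1, cov[2], runif(1)), 0); other[2] <- cov[2] - other[1]
    a <- frequencyEstimate(bs = bs, tab = other)
    b <- frequencyEstimate(bs = bs, oxbs = other)
    expect_identical(a$pH, b$pM)
    expect_identical(a$pM, b$pH)
    expect_identical(a$overshoot, b$overshoot)
  }
})
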