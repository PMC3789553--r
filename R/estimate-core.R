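# Internal vectorized estimation core.
#
# Sites are represented as an n x 6 numeric matrix with columns
#   bsC bsT oxC oxT tabC tabT
# (C = unconverted reads, T = converted reads; a zero-coverage experiment
# is equivalent to an absent one: it contributes nothing to the
# likelihood, the E-step or the M-step).

.OBS_COLS <- c("bsC", "bsT", "oxC", "oxT", "tabC", "tabT")

.obsMatrix <- function(bs = NULL, oxbs = NULL, tab = NULL) {
  pair <- function(x, what) {
    if (is.null(x)) return(c(0, 0))
    if (length(x) != 2L || anyNA(x) || any(x < 0) || any(x != round(x)))
      stop("'", what, "' must be two non-negative integer counts ",
           "c(C_reads, T_reads)", call. = FALSE)
    as.numeric(x)
  }
  m <- matrix(c(pair(bs, "bs"), pair(oxbs, "oxbs"), pair(tab, "tab")),
              nrow = 1L, dimnames = list(NULL, .OBS_COLS))
  m
}

# Coverage-weighted least squares on the implied-level equations
#   f_BS ~ p_m + p_h, f_OXBS ~ p_m, f_TAB ~ p_h,
# each equation weighted by its experiment's coverage.  With exactly two
# covered experiments this reduces to the exact pairwise solution
# (e.g. BS+TAB: p_h = f_TAB, p_m = f_BS - f_TAB).  The solution may lie
# outside the probability simplex; `overshoot` records that.
.freqCore <- function(m) {
  nb <- m[, 1L] + m[, 2L]
  no <- m[, 3L] + m[, 4L]
  nt <- m[, 5L] + m[, 6L]
  fb <- ifelse(nb > 0, m[, 1L] / nb, 0)
  fo <- ifelse(no > 0, m[, 3L] / no, 0)
  ft <- ifelse(nt > 0, m[, 5L] / nt, 0)
  nCovered <- (nb > 0) + (no > 0) + (nt > 0)

  M11 <- nb + no
  M12 <- nb
  M22 <- nb + nt
  b1 <- nb * fb + no * fo
  b2 <- nb * fb + nt * ft
  det <- M11 * M22 - M12 * M12        # > 0 iff >= 2 covered experiments
  pm <- ifelse(det > 0, (M22 * b1 - M12 * b2) / det, NA_real_)
  ph <- ifelse(det > 0, (M11 * b2 - M12 * b1) / det, NA_real_)

  list(pM = unname(pm), pH = unname(ph), nCovered = unname(nCovered),
       overshoot = unname(!is.na(pm) & (pm < 0 | ph < 0 | pm + ph > 1)),
       fBS = unname(ifelse(nb > 0, fb, NA_real_)),
       fOXBS = unname(ifelse(no > 0, fo, NA_real_)),
       fTAB = unname(ifelse(nt > 0, ft, NA_real_)))
}

# Observed-data log-likelihood: sum of independent binomial log pmfs, one
# per covered experiment, success probability = implied level.  Full pmf
# (with binomial coefficients) so values are comparable with dbinom().
.loglikCore <- function(m, pm, ph) {
  term <- function(x, n, p) {
    out <- numeric(length(x))
    i <- n > 0
    # clamp float fuzz only; genuinely out-of-range p is caught upstream
    p <- pmin(pmax(p, 0), 1)
    out[i] <- stats::dbinom(x[i], n[i], if (length(p) > 1L) p[i] else p,
                            log = TRUE)
    out
  }
  term(m[, 1L], m[, 1L] + m[, 2L], pm + ph) +
    term(m[, 3L], m[, 3L] + m[, 4L], pm) +
    term(m[, 5L], m[, 5L] + m[, 6L], ph)
}

.clipInit <- function(pm, ph) {
  eps <- 1e-6
  pu <- 1 - pm - ph
  pm <- pmin(pmax(pm, eps), 1 - 2 * eps)
  ph <- pmin(pmax(ph, eps), 1 - 2 * eps)
  pu <- pmin(pmax(pu, eps), 1 - 2 * eps)
  s <- pm + ph + pu
  list(pM = pm / s, pH = ph / s, pU = pu / s)
}

.safeRatio <- function(num, den) ifelse(den > 0, num / den, 0)

# EM for the constrained MLE on the simplex, vectorized over sites.
# E-step: expected split of the ambiguous read classes into true states
# under the current parameters; M-step: multinomial complete-data MLE
# (each level = its total expected read count / total coverage).
# With exactly two covered experiments the in-simplex frequency solution
# is the MLE and is returned as-is; EM runs at overshoot sites and at
# every three-experiment site (the over-determined least-squares
# combination is only a consistency check and initializer there — the
# likelihood, which is concave on the simplex, decides the estimate).
.emCore <- function(m, tol = 1e-10, maxIter = 500L, keepTrace = FALSE) {
  fr <- .freqCore(m)
  n <- nrow(m)
  pm <- fr$pM
  ph <- fr$pH
  pu <- 1 - pm - ph
  needEM <- fr$overshoot | fr$nCovered == 3L
  method <- ifelse(needEM, "EM", "FREQUENCY")
  method[fr$nCovered < 2L] <- NA_character_
  iterations <- integer(n)
  converged <- !is.na(method)

  bsC <- m[, 1L]; bsT <- m[, 2L]
  oxC <- m[, 3L]; oxT <- m[, 4L]
  tabC <- m[, 5L]; tabT <- m[, 6L]
  N <- bsC + bsT + oxC + oxT + tabC + tabT

  run <- which(needEM & fr$nCovered >= 2L)
  trace <- if (keepTrace) vector("list", n) else NULL
  if (length(run)) {
    init <- .clipInit(pm[run], ph[run])
    pm[run] <- init$pM; ph[run] <- init$pH; pu[run] <- init$pU
    if (keepTrace)
      for (j in run) trace[[j]] <- .loglikCore(m[j, , drop = FALSE],
                                               pm[j], ph[j])
    active <- run
    iter <- 0L
    while (length(active) && iter < maxIter) {
      iter <- iter + 1L
      a <- active
      eBS  <- bsC[a]  * .safeRatio(pm[a], pm[a] + ph[a])
      eTAB <- tabT[a] * .safeRatio(pm[a], pm[a] + pu[a])
      eOX  <- oxT[a]  * .safeRatio(ph[a], ph[a] + pu[a])
      pm2 <- (eBS + oxC[a] + eTAB) / N[a]
      ph2 <- (bsC[a] - eBS + tabC[a] + eOX) / N[a]
      pu2 <- (bsT[a] + oxT[a] - eOX + tabT[a] - eTAB) / N[a]
      delta <- pmax(abs(pm2 - pm[a]), abs(ph2 - ph[a]), abs(pu2 - pu[a]))
      pm[a] <- pm2; ph[a] <- ph2; pu[a] <- pu2
      iterations[a] <- iter
      if (keepTrace)
        for (j in a) trace[[j]] <- c(trace[[j]],
                                     .loglikCore(m[j, , drop = FALSE],
                                                 pm[j], ph[j]))
      active <- a[delta >= tol]
    }
    converged[run] <- TRUE
    converged[active] <- FALSE
    pm[run] <- pmax(pm[run], 0)
    ph[run] <- pmax(ph[run], 0)
    pu[run] <- pmax(pu[run], 0)
  }

  # in-simplex pair solutions can carry float fuzz at the boundary
  # (e.g. p_u = -5e-17 when f_BS = 1); snap into [0, 1]
  keepFreq <- which(!needEM & fr$nCovered >= 2L)
  pm[keepFreq] <- pmin(pmax(pm[keepFreq], 0), 1)
  ph[keepFreq] <- pmin(pmax(ph[keepFreq], 0), 1)
  pu[keepFreq] <- pmin(pmax(pu[keepFreq], 0), 1)

  una <- fr$nCovered < 2L
  pm[una] <- NA_real_; ph[una] <- NA_real_; pu[una] <- NA_real_
  converged[una] <- NA

  list(pM = pm, pH = ph, pU = pu, method = method,
       iterations = iterations, converged = converged,
       overshoot = fr$overshoot & !una, nCovered = fr$nCovered,
       freq = fr, trace = trace)
}

# Wilson score interval for a binomial proportion at level 1 - alpha.
.wilson <- function(x, n, alpha) {
  z <- stats::qnorm(1 - alpha / 2)
  f <- x / n
  denom <- 1 + z^2 / n
  center <- (f + z^2 / (2 * n)) / denom
  half <- z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2)) / denom
  lower <- pmax(0, center - half)
  upper <- pmin(1, center + half)
  lower[x == 0] <- 0        # endpoints are exact at the extreme frequencies
  upper[x == n] <- 1
  cbind(lower = lower, upper = upper)
}

# Count experiments whose Wilson CI around the observed frequency excludes
# the joint estimate's implied level.  Zero-coverage experiments are
# skipped.  Vectorized over sites.
.conflictCore <- function(m, pm, ph, alpha = 0.05) {
  out <- integer(nrow(m))
  implied <- list(pm + ph, pm, ph)
  for (k in 1:3) {
    x <- m[, 2L * k - 1L]
    n <- x + m[, 2L * k]
    i <- which(n > 0 & !is.na(implied[[k]]))
    if (length(i)) {
      ci <- .wilson(x[i], n[i], alpha)
      lev <- implied[[k]][i]
      out[i] <- out[i] + (lev < ci[, "lower"] | lev > ci[, "upper"])
    }
  }
  out
}
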