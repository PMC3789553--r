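---
title: "Methods: joint maximum-likelihood estimation of 5-mC and 5-hmC levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint maximum-likelihood estimation of 5-mC and 5-hmC levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointMeth)
```

## The observation model

At a single cytosine site, three quantities describe the population of
molecules: the 5-methylcytosine level $p_m$, the 5-hydroxymethylcytosine
level $p_h$, and the unmethylated level $p_u = 1 - p_m - p_h$. Each
sequencing protocol observes a binomial draw whose success probability
is a fixed linear functional of $(p_m, p_h)$, the *implied level*:

* BS-seq: both 5-mC and 5-hmC resist bisulfite conversion, so a C read
  occurs with probability $p_m + p_h$;
* oxBS-seq: chemical oxidation converts 5-hmC before bisulfite
  treatment, so a C read occurs with probability $p_m$;
* TAB-seq: glucosylation protects 5-hmC while TET oxidation exposes
  5-mC, so a C read occurs with probability $p_h$.

For experiments $e$ with C-read counts $x_e$ and coverages $n_e$, the
observed-data log-likelihood is
$\ell(p_m, p_h) = \sum_e \log \mathrm{Binom}(x_e;\, n_e,\, \pi_e(p_m, p_h))$
with $\pi_e$ the implied level. The experiments are assumed independent
(separate library preparations of the same sample), coverage is taken as
fixed, and conversion chemistry is taken as perfect — the model has no
parameters for bisulfite non-conversion, incomplete oxidation or TET
inefficiency. Real data violate the last assumption to varying degrees;
the conflict flags (below) are the diagnostic for that, not a
correction.

## Frequency solution, overshoot, and the constrained MLE

With exactly two covered experiments the implied-level equations are
exactly determined by the observed frequencies $f_e = x_e / n_e$; for
BS + TAB, $\hat p_h = f_{TAB}$ and $\hat p_m = f_{BS} - f_{TAB}$. This
plug-in solution can leave the probability simplex — a negative
subtraction result, or directly measured levels summing over one — and
such *overshoot* is common at realistic coverages because the two
experiments sample independently. When the plug-in solution does lie in
the simplex it is the unconstrained MLE, and the package returns it
untouched (`method = "FREQUENCY"`).

At overshoot sites the MLE lies on the simplex boundary. It is computed
by expectation-maximization with latent read classes: the number of
BS-seq C reads that originate from 5-mC (vs 5-hmC), the number of
TAB-seq T reads that originate from 5-mC (vs unmethylated), and the
number of oxBS-seq T reads that originate from 5-hmC (vs unmethylated).
The complete-data likelihood is a multinomial over the six read classes,
so the E-step splits each ambiguous class proportionally — e.g.
$E[\text{BS C reads from 5-mC}] = x_{BS}\, p_m / (p_m + p_h)$ — and the
M-step divides each state's total expected reads by the total coverage.
Standard EM theory gives monotone non-decreasing observed-data
likelihood; the test suite asserts this trace on every EM run it
performs.

### Three experiments

With all three experiments the frequency system is over-determined. A
coverage-weighted least-squares combination of the three equations is
used *only* for overshoot classification and as the EM starting point;
the returned estimate always comes from the likelihood, because the
least-squares point weights experiments by coverage alone while the
binomial information depends on the level itself. The observed
log-likelihood is concave on the simplex (each term is the log of a
binomial in a linear functional of the parameters), so EM converges to
the global constrained MLE. An exhaustive grid search over the simplex
(`gridOracle()`, step $10^{-3}$) is the independent guard that the EM
answer maximizes the stated likelihood, for pairs and triples alike.

## Numerical choices

* **Initialization.** EM starts from the frequency solution clamped
  componentwise into $[10^{-6}, 1 - 2 \times 10^{-6}]$ and renormalized.
  This is deterministic, close to the unconstrained optimum, and keeps
  the starting likelihood finite and every E-step denominator positive.
* **0/0 in the E-step.** If a responsibility denominator (e.g.
  $p_m + p_h$) is zero the corresponding expected count is defined as
  zero; with the clamped initializer this arises only for
  zero-coverage (absent) experiments.
* **Convergence.** Iteration stops when the largest absolute parameter
  change falls below `tol` ($10^{-10}$ by default, comfortably beyond
  the 6-decimal output precision) or after `maxIter` (500) iterations,
  in which case `converged = FALSE` is reported rather than an error.
  Near-tied overshoot sites can have EM contraction rates close to 1;
  the iterate is then still within $\sim 10^{-6}$ of the boundary
  optimum even when the cap is hit, which the oracle-agreement tests
  cover.
* **Boundary fuzz.** In-simplex pair solutions are snapped into
  $[0, 1]$ (float residue of order $10^{-16}$ otherwise leaks into
  $p_u$), and Wilson interval endpoints are exact 0/1 at observed
  frequencies 0/1.
* **Tie-breaking.** The grid oracle resolves likelihood ties at the
  smallest $p_m$, then smallest $p_h$ — determinism for tests, nothing
  more.
* **Degenerate sites.** A site covered by fewer than two experiments
  cannot identify the three-way split. The estimator refuses to invent
  one: scalar calls error, and the vectorized path emits `NA` for the
  unidentified components, retaining a directly measured margin where
  one exists (oxBS alone still identifies $p_m$, TAB alone $p_h$; BS
  alone identifies only the sum, so nothing individually).

## Conflict flagging

After estimation, each covered experiment gets a two-sided Wilson score
interval at level $1 - \alpha$ (default $\alpha = 0.05$) around its own
observed frequency; the site collects one conflict per experiment whose
interval excludes the joint estimate's implied level. The Wilson
interval was chosen over Wald or Clopper–Pearson because conflicts
concentrate at extreme frequencies (0 and 1) where Wald collapses and
Clopper–Pearson over-covers; both the construction and $\alpha$ are
parameters, since different datasets warrant different stringency. The
package reports per-site counts and a global summary only — an excess
of strongly inconsistent sites *suggests* systematic error (e.g.
incomplete conversion), but no verdict is issued because no error model
is fitted.

## The file format

Input tracks are methcounts-style 6-column TSV: chromosome, 0-based
cytosine position, strand, context token, level (C-read fraction) and
coverage. C-read counts are recovered as `level * coverage` rounded half
away from zero — the rounding rule is part of the format contract and
round-trips any counts written in this convention. Coordinates are
strand-resolved single cytosines; collapsing symmetric CpG pairs is
left to preprocessing. Output adds $p_m$, $p_h$, $p_u$ at fixed 6
decimals and the conflict count, with `NA` for unidentified fields.

## What the simulation harness emulates

`runOvershootStudy()` regenerates the estimator-comparison study: for
every valid $(p_m, p_h)$ combination on a step-0.05 grid and each
per-experiment coverage, it draws independent binomial counts for the
chosen experiment pair (BS + TAB by default; the BS + oxBS study is the
mirror image with $p_m$ and $p_h$ exchanged), applies both estimators,
and averages the 5-hmC error over the overshoot replicates — the only
replicates where the methods differ. Both absolute error
$|\hat p_h - p_h|$ and relative error $|\hat p_h - p_h| / p_h$ (where
$p_h > 0$) are reported, and the headline summary is the maximum percent
reduction over grid points in mean relative error,
`errorReductionAtOvershoot()`.

The frequency method's estimate at overshoot replicates follows naive
practice deliberately: the directly measured frequency ($f_{TAB}$) is
kept as-is and a negative subtraction result is clipped to zero, with no
renormalization. This convention affects the comparison and is therefore
fixed and documented rather than configurable.

Defaults are 10 000 replicates per grid point and coverages of order
5–20, i.e. low-coverage whole-genome scale where overshoot is common;
the acceptance script runs coverages 10 and 5 with 10 000 replicates,
and the exhaustive-enumeration cross-checks in the tests run at coverage
≤ 10 where the full joint count distribution is tractable. The generator
draws with a single seeded RNG stream in a fixed order (coverage-major,
grid-point-major, experiments in BS/OXBS/TAB order), so studies are
bit-reproducible given the seed and RNG (recorded in the output header).

What the generator does *not* emulate: systematic conversion errors,
coverage heterogeneity across sites, correlation between neighbouring
CpGs, or mapping artefacts. Passing the simulation-based tests therefore
demonstrates correct estimation under binomial sampling noise — the
model's own assumptions — not robustness to protocol-specific biases in
real libraries.

## Limitations

* Strictly per-site: no smoothing or information sharing across sites.
* No modelling of conversion error rates; strongly inconsistent sites
  are flagged, not corrected.
* No differential methylation testing; the output is a level track.
* The EM iteration cap can be reached at near-tied overshoot sites
  (contraction rate near 1); estimates remain accurate to well below
  output precision, but `converged` should be checked when `tol` is
  tightened further.
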