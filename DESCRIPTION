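Package: jointMeth
Title: Consistent Joint Estimation of 5-Methylcytosine and
    5-Hydroxymethylcytosine Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint maximum-likelihood estimation of per-site
    5-methylcytosine (5-mC) and 5-hydroxymethylcytosine (5-hmC) levels
    from any two or all three of bisulfite sequencing (BS-seq),
    oxidative bisulfite sequencing (oxBS-seq) and Tet-assisted
    bisulfite sequencing (TAB-seq) read counts.  Naive subtraction of
    per-experiment frequencies can yield negative levels or levels
    summing over one ("overshoot"); this package computes the
    constrained maximum-likelihood estimate on the probability simplex
    via an expectation-maximization algorithm over latent read classes,
    flags sites whose joint estimate conflicts with per-experiment
    binomial confidence intervals, reads and writes per-site count
    tracks in a methcounts-style tab-delimited format, and includes a
    seeded binomial simulation harness for comparing the joint
    estimator against the frequency method at overshoot sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MethCountSet-methods.R'
    'estimate-core.R'
    'estimate-site.R'
    'io-methcounts.R'
    'jointMeth-package.R'
    'simulate.R'
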