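Package: mtdrift
Title: Random Genetic Drift Analysis of Mitochondrial DNA Heteroplasmy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical tools for studying the segregation of pathogenic
    mitochondrial DNA (mtDNA) heteroplasmy through the germline bottleneck.
    Implements the Kimura distribution of allele frequency under pure random
    genetic drift (fixation masses, density, distribution function, moments
    and sampling), moment-based estimation of the bottleneck parameter from
    cohorts of offspring mutant-load measurements, Monte-Carlo confidence
    intervals and a parametric-bootstrap Kolmogorov-Smirnov goodness-of-fit
    test, a Wright-Fisher bottleneck simulator with a single-cell sampling
    and assay-noise model, and single-cell dispersion statistics (pool
    summaries, mean-versus-SD regression, one-way intraclass correlation,
    transmission rate under a detection threshold).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
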