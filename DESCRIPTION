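Package: sfstep
Title: Stepwise Demographic Inference from the Site-Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a stepwise history of effective population sizes from a
    folded or unfolded site-frequency spectrum (SFS). Each coalescent interval
    is assigned its own effective size; closed-form expressions give the
    expected SFS under any such piecewise-constant history, and a composite
    Poisson likelihood is maximised by Newton iteration with greedy or
    exhaustive stepwise breakpoint selection. Also computes
    per-frequency-class allele age moments and the long-term effective
    population size experienced by alleles of each frequency, for folded and
    unfolded spectra, and ships a coalescent simulator (level-indexed and
    time-indexed piecewise-constant demographies, infinite-sites mutation)
    used as a Monte-Carlo validation oracle and synthetic-data source.
    Bootstrap resampling of the SFS yields pointwise confidence bands on the
    inferred history.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
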