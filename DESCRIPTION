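Package: stairsfs
Title: Multi-Epoch Coalescent Skyline Inference from Site Frequency Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers piecewise-constant effective population size history from a
    single folded or unfolded site frequency spectrum (SFS). A flexible
    multi-epoch coalescent model with one scaled mutation rate per coalescent
    interval is fitted by composite (multinomial) likelihood; overfitting is
    controlled by train/test subsampling of sites and by constraining epoch
    breakpoints to a random subset of candidate positions, with the breakpoint
    count selected by out-of-sample goodness of fit. The final estimate is the
    median trajectory of an ensemble of subsample fits, with percentile
    confidence bands. Includes a coalescent simulator for piecewise-constant
    and exponential-growth demographies (ms-style scaling) and an exact
    multinomial generator for the inference model itself, for validation and
    power studies. Supports masking unreliable SFS classes such as singletons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
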