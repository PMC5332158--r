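Package: replispan
Title: Replicative Lifespan Analysis for Symmetrically Dividing Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-cell replicative lifespan
    (RLS) data from catch-channel microfluidic assays of fission yeast.
    Generates synthetic lineages under exponential (constant-hazard) or
    Gompertz mortality with bilinear (NETO) cell growth, renders and
    quantifies kymograph image stacks (drift registration, length tracing,
    local-minima division calling, ejection screening), fits weighted
    exponential and Gompertz survival models with closed-form replicative
    lifespan and bootstrap confidence intervals, and classifies populations
    as aging versus non-aging, including death-aligned phenotype analyses
    and RLS contour maps over the hazard coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    minpack.lm,
    nortest,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
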