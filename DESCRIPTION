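Package: ambiflux
Title: Alternative Optima in Context-Specific Metabolic Model Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies and reduces the ambiguity caused by alternative optima
    in context-specific metabolic model predictions. Implements
    least-absolute-deviation regularized flux fitting of gene expression data
    (RegrEx-LAD), sampling of its alternative optimal flux distributions
    (alternative optima sampling), parsimonious core-expansion network
    extraction (CorEx), enumeration of maximally different alternative optimal
    networks (AltNet, including a confidence-group mode compatible with CORDA
    classifications), and downstream uncertainty statistics: Shannon entropy of
    sampled fluxes, fixed-direction fractions of reversible reactions, Hamming
    distances between reconstructions, non-core reaction classification,
    pathway ambiguity scores, and metabolic-task feasibility testing. Linear
    and mixed-integer programs are solved with the HiGHS solver through SciPy;
    quadratic flux-cone projections use 'quadprog'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    quadprog,
    reticulate,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
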