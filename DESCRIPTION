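Package: gcpotts
Title: Multiscale Spatial Simulation of the Germinal Center Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based, multiscale simulator of the germinal center (GC)
    reaction. B cells are represented as multi-pixel agents on a Cellular
    Potts lattice, cycling between the dark zone and light zone under opposing
    CXCL12/CXCL13 chemokine gradients maintained by reaction-diffusion.
    Each B cell carries a stochastic intracellular signalling network
    (CD40, AKT, FOXO1, cRel, MYC, AP4, CXCR4, BLIMP1 and partners) advanced
    with Gillespie's direct method, which drives somatic hypermutation,
    pMHCII-proportional positive selection, death-timer apoptosis, AP4-gated
    proliferative bursts, and plasma-cell output. An analysis layer computes
    population turnover, inter-zonal migration times, burst statistics by
    affinity bin, clonal composition, and molecular snapshot profiles from
    structured per-cell logs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
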