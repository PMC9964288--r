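Package: waterscape
Title: Space-Psychology-Behavior Evaluation of Waterfront Green Space
    Landscape Aesthetics
Version: 0.1.0
Authors@R: person("waterscape", "developers", role = c("aut", "cre"),
    email = "maintainers@waterscape.dev")
Description: Quantifies the landscape aesthetic value of urban waterfront
    green spaces along three coupled dimensions. The spatial dimension
    computes twelve formula-defined indicators from categorical land-cover
    rasters, elevation/surface grids and panoramic images (Shannon
    diversity, Pielou evenness, hemeroby, fragmentation, vertical layer
    superposition, colorfulness, terrain position, profile curvature, sky
    fraction, tridimensional green volume, canopy density, relief
    amplitude), normalizes them and grades parks by exact Jenks natural
    breaks. The psychological dimension derives emotional values, relative
    evaluation rates and relative emotional values from review text via a
    pluggable sentiment scorer, with a rate-emotion regression and
    five-sense word frequencies. The behavioral dimension summarizes
    heat-map snapshots, Gaussian kernel densities of visitor points and
    behavior observations. A coupling-coordination model (C, T,
    D = sqrt(C*T), ten-level ladder) relates the three subsystems. A
    synthetic-scene generator produces every input with known ground truth
    so each stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
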