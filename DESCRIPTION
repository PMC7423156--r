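Package: tractoprint
Title: Connectivity Blueprints and Cross-Brain Divergence on Synthetic Tractography Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for comparative diffusion-MRI tractography:
    seeded synthetic fiber-orientation phantoms with known bundle ground truth,
    probabilistic and deterministic streamline tractography under
    seed/waypoint/exclusion/termination protocols, connectivity-based k-means
    parcellation of white-matter regions with permutation-based reliability
    statistics, vertex-by-tract connectivity blueprints on a gray/white border
    surface, and cross-brain comparison of connectivity fingerprints by
    Kullback-Leibler divergence, including minimum-divergence maps, best-match
    fingerprints, tract-swap difference maps, and Kolmogorov-Smirnov
    comparison of divergence distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    RNifti,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
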