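Package: ptacube
Title: Partial Triadic Analysis of Space-Time Tree-Ring Datacubes
Version: 0.9.0
Authors@R:
    person("Forest", "Biometrics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the partial triadic analysis (PTA, STATIS family) of
    three-way tree-ring datasets (trees x ring descriptors x years): ingestion
    and validation of long-format ring tables into a datacube, per-table
    standardization, the interstructure (vectorial correlation between tables
    and its non-centered eigen-analysis), the weighted compromise table and
    its PCA, the intrastructure (supplementary projection of each table with
    quantile-envelope outlier detection), and Moran's I permutation
    correlograms with Holm correction for the spatial analysis of compromise
    scores. Includes a synthetic datacube generator with known latent spatial
    and temporal structure for recovery benchmarking, and an end-to-end
    pipeline with serialized, reproducible outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
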