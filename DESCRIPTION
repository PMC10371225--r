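Package: receptome
Title: Interregional Neurotransmitter Receptor Similarity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses the receptome, a region-by-region matrix of
    interregional neurotransmitter receptor and transporter (NTRM) fingerprint
    similarity derived from parcellated PET density maps. Provides diffusion-map
    embedding of similarity networks with normalized-angle affinity kernels,
    spatial-autocorrelation-preserving null models (variogram matching and
    spherical spin permutation), signed-network Leiden community detection with
    z-rand consensus and a modular stability score, group-consensus functional,
    structural, and microstructural connectivity builders, row-wise coupling
    statistics across cytoarchitectural classes, and a seeded synthetic-data
    generator that emulates the statistical structure of parcellated brain maps
    so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
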