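Package: aescreen
Title: Autoencoder Descriptors for Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening with autoencoder-compressed
    molecular fingerprints. Provides a tied-weight sigmoid autoencoder that
    reduces 1024-feature extended-connectivity count fingerprints to
    low-dimensional descriptors, continuous and binary Tanimoto similarity
    searching, a simulated screening protocol (random reference selection,
    ranked retrieval, recall at top 1%/5% cutoffs), recall summary tables
    with best-method counts, Kendall coefficient-of-concordance analysis of
    method rankings across activity classes, and a seeded generator of
    synthetic count-fingerprint datasets with calibrated intra-class
    homogeneity emulating MDDR-style benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
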