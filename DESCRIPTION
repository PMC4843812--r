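Package: refstab
Title: Reference Gene Stability Analysis for qRT-PCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening and validation of candidate reference (housekeeping)
    genes for quantitative real-time PCR. Implements the three standard
    stability algorithms on Ct tables -- geNorm (expression stability M,
    stepwise elimination, normalization factors and pairwise variation
    Vn/n+1), NormFinder (model-based inter/intra-group variance
    decomposition into a stability value) and BestKeeper (descriptive
    Ct statistics, SD-based exclusion, index correlations) -- together
    with geometric-mean consensus ranking of the three orderings,
    FPKM-based candidate screening from RNA-seq expression tables,
    target-gene normalization against chosen references, and a synthetic
    Ct/FPKM data generator with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
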