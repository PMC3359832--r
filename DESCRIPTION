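Package: pbsc
Title: Pathway-Based Similarity Comparison for Drug Signature Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches paired (pre/post treatment) expression profiles against a
    bank of reference drug-perturbation signatures, scored per biological
    pathway with a signed Kolmogorov-Smirnov connectivity statistic and
    ranked by signed pathway counts, in the style of Connectivity-Map
    queries. Includes microarray-style preprocessing (log2 transform,
    quantile normalization, signal-to-noise filtering), fold-change
    differential calling, a gene-set enrichment gate with a permutation
    null, per-pathway connectivity scoring against ranked reference
    profiles, top-k instance reports, and a synthetic-data generator with
    planted drug effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
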