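Package: integromics
Title: Integrated Multi-Omics Differential Abundance and Pathway Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for two-group multi-omics liver studies:
    per-layer differential abundance (TMM-normalized count layers tested by
    equal-variance t-tests, presence-filtered and sequentially imputed protein
    intensities, VIP-gated metabolites), knowledge-base-driven right-tailed
    Fisher over-representation over single and combined omics layers with a
    direct-connection requirement, upstream-regulator activation calling by
    sign-consistency z-scores, inverse-expression miRNA-target pairing, and
    GWAS-trait overlap reporting. Ships a synthetic-study generator with
    planted pathway, regulator, and miRNA signals so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    mixOmics,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
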