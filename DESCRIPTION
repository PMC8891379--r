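Package: pahrisk
Title: Dietary Exposure and Cancer Risk Assessment for PAH Congeners in
    Infant Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for summarizing left-censored concentration surveys of
    the 16 EPA-priority polycyclic aromatic hydrocarbons (PAHs) in
    cereal-based infant foods and for turning them into health-risk
    estimates. Implements half-LOD substitution for non-detects,
    per-product-type summary tables with regulatory sums (PAH4, total
    PAH16) and EU compliance checks, toxic-equivalency (TEF) scoring to
    benzo[a]pyrene-equivalent concentrations (BEC), deterministic and
    Monte Carlo estimated daily intake (EDI) and incremental lifetime
    cancer risk (ILCR) with percentile reporting and risk-zone
    classification, a synthetic censored-data generator that emulates the
    survey design (9 product types x 2 brands), and heat-map clustering of
    congener profiles with Pearson correlation distance and average
    linkage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    grid,
    jsonlite,
    pheatmap,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
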