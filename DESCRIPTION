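Package: ror50
Title: PAM50 Subtyping and Risk-of-Recurrence Scoring for Paired Tumor Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Research-based PAM50 intrinsic subtyping and risk-of-recurrence
    (ROR) scoring for early breast cancer expression data. Implements
    ER-balanced (60/40 weighted) per-gene centering driven by a bimodal ESR1
    mixture call, nearest-centroid subtype assignment by Pearson correlation
    on the 46-gene reduced panel, an 18-gene proliferation score, the linear
    ROR formula with node-status-dependent risk categorization, concordance
    statistics for comparing two assays of the same cohort (r-squared,
    risk-group discordance, subtype confusion matrices, per-gene
    cross-platform correlation), and a seeded tumor-purity simulator that
    generates paired macrodissected-like and bulk-like cohorts with ground
    truth to study normal-tissue contamination of subtype calls and ROR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mclust,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
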