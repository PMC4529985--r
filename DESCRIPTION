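Package: proteoscreen
Title: Integrative Proteogenomic Screening for Treatment-Specific Gene
    Up-Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes specifically up-regulated by a treatment by
    integrating transcriptomic and proteomic evidence. Provides the
    rank-products statistic with permutation-based estimation of the
    percentage of false positives (pfp), a fold-change specificity screen
    against a comparator treatment, protein-abundance concordance testing
    on arcsinh-transformed label-free intensities, cross-validation of
    candidates against high-confidence interaction-network partners, and
    ranked gene-set enrichment using the minimum-hypergeometric statistic
    with Benjamini-Hochberg correction. Includes a synthetic-data
    generator that plants treatment-specific, shared and null genes so
    the full pipeline can be exercised and benchmarked without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
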