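Package: regulonbench
Title: Benchmarking Regulon-Inferred Regulatory Activity Against mRNA
    Abundance for Predicting Gene Essentiality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask whether transcription-factor activity inferred from
    gene regulatory networks predicts sensitivity to CRISPR gene inhibition
    better than the regulator's own mRNA abundance. Parses regulon tables in
    several common dialects (ARACNe-style likelihood/MOR tables, GENIE3-weight
    tables without signs, curated confidence-graded tables), implements six
    activity scoring methods (univariate and multivariate linear models,
    single-layer analytic rank-based enrichment, weighted sum, weighted mean,
    and a z-score consensus), applies essentiality filters on CHRONOS-like
    gene-effect scores, and provides the statistical comparison layer:
    per-gene Pearson correlations with significance binning, common-language
    effect sizes against binary essentiality, matched-versus-mismatched
    network ranking tests, and adjusted R-squared variance decomposition.
    A synthetic-cohort generator with planted ground truth makes every stage
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
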