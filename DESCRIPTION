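Package: strainshare
Title: Strain-Level Analysis of Mother-to-Infant Oral Microbiota Transmission
Version: 0.1.0
Authors@R: person("strainshare", "developers", email = "strainshare@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying vertical transmission of oral bacteria from
    mothers to infants at amplicon-sequence-variant (ASV) resolution. Provides
    a feature-table data model with OTU collapsing, rarefaction and alpha
    diversity; shared-ASV statistics for biological and unrelated mother-infant
    pairs with a per-OTU sharing index; square-root Bray-Curtis distances,
    principal coordinate analysis, an origin-aware (shared vs nonshared)
    community table and hierarchical clustering of infant microbiota; a
    hand-implemented nonparametric battery (Mann-Whitney U, Kruskal-Wallis with
    eta-squared effect size, Benjamini-Hochberg FDR, Steel-Dwass all-pairs
    comparisons); clinical-covariate derivations (Kaup index, weight
    categories) and cohort summary tables; and a seeded synthetic-cohort
    generator that plants covariate-dependent transmission with full ground
    truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    jsonlite
Config/testthat/edition: 3
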