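Package: gnotofun
Title: Comparative Functional Profiling of Defined Microbial Consortia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for contrasting the predicted metabolic potential of
    defined (gnotobiotic) microbial consortia from KEGG Ortholog (KO)
    annotations: KO-level set algebra and unique-KO breakdowns, module
    completeness scoring against gut metabolic module (GMM) and KEGG-style
    module definitions with threshold-based presence calls, prevalence
    tables, pairwise chi-squared and dissimilarity statistics, reporter-score
    pathway enrichment with Monte-Carlo background correction, and
    nonparametric two-group metabolomics comparison with false discovery
    rate control.  A synthetic-data generator with planted ground truth
    makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
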