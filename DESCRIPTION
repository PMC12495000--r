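Package: limnoco
Title: Simulation and Co-Occurrence Cohort Analysis of Freshwater Metagenome Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the ecology of freshwater prokaryotes from
    competitive-mapping depth profiles: genome-size estimation and
    ANI-based dereplication of genome catalogs, truncated-average-depth
    (TAD) relative abundance with genome-equivalent normalization,
    SparCC compositional co-occurrence networks with bootstrap p-values,
    modularity-based cohort detection tested against degree-preserving
    rewired nulls, weighted environmental preference scores, and KEGG
    module completeness scoring for metabolic complementarity. A
    synthetic-community generator with exported ground truth makes every
    stage testable end to end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
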