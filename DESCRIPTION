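Package: reporterMet
Title: Reporter Metabolite Analysis and Promoter Motif Enrichment for
    Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Network-guided transcriptome analysis. Scores metabolites in a
    genome-scale metabolic network by the collective differential expression
    of their neighboring enzyme-coding genes (reporter metabolites), using
    inverse-normal Z aggregation with a sampled-background correction.
    Downstream stages test promoters of the up- or down-regulated neighbor
    gene sets for transcription-factor binding motif enrichment against a
    metabolic-gene background (log-odds PWM scanning over a second-order
    Markov model, one-tailed Fisher tests, Storey q-values), compare reporter
    sets across contrasts by Jaccard distance with hierarchical clustering,
    and correlate neighbor-gene centroid expression with phenotypes. Includes
    a synthetic-data generator that emulates the assumed input structure so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    limma,
    Biostrings,
    ape,
    jsonlite,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
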