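Package: ndprio
Title: Integrative Candidate-Gene Prioritization for Neurodevelopmental
    Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing candidate genes in trio-based
    targeted-sequencing studies of neurodevelopmental disorders.
    Classifies trio variants by inheritance and functional class
    (protein-truncating and deleterious missense), applies population
    allele-frequency filters, detects inherited X-linked hemizygous
    variants, and tabulates per-gene qualifying-variant counts.
    Gene-level association combines de novo and case-control evidence
    through Gamma-Poisson Bayes factors in the TADA framework, with
    posterior probabilities and Bayesian false-discovery-rate q-values.
    Downstream modules catalogue known versus novel candidate genes,
    test co-expression between novel and known candidates with a
    permutation null, build seed-gene functional networks from
    protein-protein-interaction and co-expression evidence, and compare
    gene-constraint (pLI, RVIS) percentiles between gene sets. A
    synthetic-data module generates cohort, expression, interaction,
    and constraint inputs with known ground truth for end-to-end
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
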