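Package: coexcons
Title: Cross-Species Gene Co-Expression Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Coexcons", "Developers", email = "coexcons@example.org",
           role = c("aut", "cre"))
Description: Builds vote-counting gene co-expression maps from compendia of
    expression datasets, compares them between two species through the number
    of commonly co-expressed genes (CCG) of homologous gene pairs, extracts
    directed networks at a percentage threshold and computes differential
    connectivity (DiffK), and evaluates tissue, pathway and disease gene sets
    with four conservation parameters (co-expression conservation,
    differential connectivity, duplication ratio, non-homolog ratio) plus a
    permutation-based candidate-gene association. Includes a synthetic
    two-species world generator with tunable module preservation so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
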