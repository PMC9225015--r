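Package: dubnet
Title: Multi-Omics Evidence Integration for Deubiquitinase Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers gene function for deubiquitinating enzymes (DUBs) by
    integrating four evidence streams computed from cancer cell-line panels:
    CRISPR-screen co-dependency profiles with gene-set over-representation,
    lineage-specific essentiality contrasts, proteomics co-expression,
    compiled protein-protein interaction databases, and perturbation-signature
    similarity (tau) flags. Each DUB-gene pair receives a 0-4 evidence count
    summing the streams in which it is significant, and positively
    co-dependent ubiquitin-transferase partners are extracted into a
    DUB-E3-ligase network. A synthetic-data generator with planted complexes,
    lineage effects and true interaction edges supports calibration and
    recovery testing without large public downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
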