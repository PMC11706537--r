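Package: isofusion
Title: Multi-Omics Integration for Isoform Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology term memberships for transcript isoforms by
    integrating isoform expression profiles, sequence features and protein-protein
    interaction (PPI) networks. Isoform-isoform interactions are inferred from
    gene-level PPIs with a multi-input multi-output autoencoder trained under
    cycle-consistency and adversarial objectives; each omics view is then
    classified with a graph convolutional network over a cosine-similarity graph,
    and the per-view label distributions are fused through a cross-omics outer
    product tensor fed to a label-correlation network. Gene-level annotations
    supervise isoform-level predictions through a multiple-instance assumption:
    a gene's annotation is carried by its best-scoring isoform. Includes a
    synthetic multi-omics generator with planted functional modules for
    end-to-end validation, gene/homolog-group aware data splitting, and
    per-term AUC/AUPRC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
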