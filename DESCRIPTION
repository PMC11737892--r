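Package: sparsego
Title: Knowledge-Primed Sparse Neural Networks for Interpretable Cell
    Status Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains sparse neural networks whose connectivity is
    pruned by prior biological knowledge: Gene Ontology annotations wire genes
    to GO-term nodes and transcription-factor binding tables wire genes to TF
    nodes, so every hidden unit corresponds to a named biological entity.
    Supports multi-class cell type annotation with open-set (novel cell type)
    detection, a regression mode for continuous cell states such as senescence
    scores, reference-based per-gene contribution scores with an exact
    completeness property, weight tracing of GO-term and TF contributions,
    in-silico single-gene perturbation screens for state-shifting candidate
    genes, de-novo TF-target inference by latent-space perturbation, and a
    negative-binomial synthetic-data generator with planted gene programs for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
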