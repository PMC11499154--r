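Package: clonoscape
Title: Dominant T-Cell Receptor Clonotype Selection from Single-Cell
    Multi-Omic Data
Version: 0.1.0
Authors@R:
    person("Clonoscape", "Developers", email = "maintainers@clonoscape.dev",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for selecting a dominant
    antigen-specific T-cell receptor (TCR) clonotype from targeted
    single-cell multi-omic data. Implements molecule-level UMI error
    correction (recursive substitution error correction and
    distribution-based error correction), barcode-rank cell calling by
    second-derivative knee detection, sample-tag demultiplexing with
    multiplet exclusion, paired-chain clonotype construction from AIRR
    rearrangements, counts-per-million expression normalization with
    CD8/CD4/FOXP3 gating, PCA and UMAP embedding, a deterministic surrogate
    for TCR-peptide binding-score prediction, dominant-clonotype selection
    by cell count with binding score as tie-breaker, and LDH cytotoxicity
    assay statistics (percent specific lysis, per-donor summaries, one-way
    ANOVA with Tukey HSD). A synthetic-data generator with planted ground
    truth makes every stage testable without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    uwot
Suggests:
    cluster,
    Matrix,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
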