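Package: synaptomics
Title: Soma-Synapse Multi-Omics Integration of Transcriptome, Translatome
    and Proteome
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates matched RNA, ribosome-associated RNA and protein
    abundance measurements across subcellular compartments (total homogenate
    versus synaptosome) and age groups. Provides compartment-enrichment
    quadrant maps with Fisher's-method p-value combination, translational
    efficiency ratios from ribosome-associated RNA, per-gene
    protein-transcript decoupling scores, compartment-coupling correlation
    trajectories across ages, gene-set enrichment on per-gene statistics
    (set-versus-background t-tests and hypergeometric overrepresentation),
    and list-overlap contingency comparisons. Includes a synthetic-data
    generator emulating a three-age, two-compartment, three-layer study
    design with programmed class structure and ground truth, so every stage
    of the pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    knitr
biocViews: Transcriptomics, Proteomics, GeneExpression, Coverage,
    DifferentialExpression, GeneSetEnrichment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
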