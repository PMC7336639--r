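Package: musclecomm
Title: Single-Cell Muscle Atlas Processing and Ligand-Receptor
    Communication Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing pipeline for droplet-based single-cell RNA-seq of
    human skeletal muscle: quality-control filtering on UMI counts and
    mitochondrial content, log-normalization with technical-covariate
    regression (10x chemistry, genes detected per cell), shared-nearest-
    neighbor graph clustering with marker-based cell-type annotation,
    Wilcoxon rank-sum marker detection with Benjamini-Hochberg correction,
    and a ligand-receptor cell-communication model that scores curated
    ligand-receptor pairs as products of mean receptor expression in a
    focal population and mean ligand expression in every other cell type,
    row-standardized across senders. Includes a negative-binomial
    synthetic-atlas generator with planted marker genes and ligand-
    receptor circuits for validation.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
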