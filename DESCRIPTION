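Package: magqc
Title: Alignment-Free Quality Prediction for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the completeness and purity of metagenomic bins
    without reference alignment or marker genes. Contigs are cut into
    fixed-length fragments, compositional signatures (Karlin tetranucleotide
    relative abundances, Markov-model z-scores for tri- and tetranucleotides,
    tetranucleotide frequency profiles and GC content) are computed per
    fragment, and the distributions of all-against-all intra-bin fragment
    distances are summarised into a fixed predictor schema. Tiered random
    forests with log/PCA preprocessing and cross-validated linear calibration
    map these predictors to completeness and purity percentages; bins lacking
    long contigs fall back to models trained without the missing feature
    blocks. Includes gold-standard labelling from known contig origins,
    evaluation metrics, a QDA-based fragment-length optimiser, and a
    synthetic mock-bin generator with exact ground truth for training and
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    MASS,
    methods,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
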