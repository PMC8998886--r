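Package: metabnet
Title: Metabolite Abundance Prediction from Transcriptomics via
    Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds bipartite metabolite-transcript co-occurrence networks
    from paired metabolomics/transcriptomics data (all-pairs Pearson
    correlation with a p-value gate, Data Processing Inequality pruning over
    metabolite-metabolite-transcript triplets, and bootstrap edge
    likelihoods) and applies them to expression-only datasets to predict
    relative metabolite abundances as rank-based Normalized Enrichment
    Scores, sample-by-sample or for two-group contrasts. Includes the
    validation machinery used to benchmark such networks (repeated
    split-half prediction, cross-dataset scoring with one-tail Wilcoxon
    summaries, Benjamini-Hochberg correction, and a degree-proportional
    shuffled-network null) plus a linear-Gaussian latent-factor simulator
    of paired omics datasets with planted, recoverable correlation
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
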