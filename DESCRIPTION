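Package: mockbench
Title: Benchmarking Bias in Full-Length 16S rRNA Mock Community Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking full-length 16S rRNA gene amplicon
    workflows against defined bacterial mock communities. Provides a
    mechanistic forward simulator of extraction, PCR amplification (with
    G+C-dependent efficiency) and sequencing for defined communities, and
    the downstream evaluation stack: feature filtering, de novo OTU
    clustering at an identity threshold, identity-threshold species
    assignment, 16S gene copy-number and genome-size normalization, alpha
    diversity (Shannon entropy, Pielou evenness, Faith phylogenetic
    diversity, observed features) with rarefaction, and preset-versus-
    observed bias attribution via log2 fold changes, G+C regression and
    Kruskal-Wallis group contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'metadata.R'
    'simulate.R'
    'features.R'
    'normalize.R'
    'diversity.R'
    'bias.R'
    'io.R'
    'mockbench-package.R'
    'pipeline.R'
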