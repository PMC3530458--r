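Package: vinemap
Title: Vineyard Microbiome Fingerprint Processing, Sampling Design and
    Mixed-Model Community Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processes ARISA (automated ribosomal intergenic spacer
    analysis) electropherogram peak tables into filtered, binned
    sample-by-OTU fluorescence matrices; generates Theory-of-Sampling
    vineyard sampling designs by lot linearization and tests for
    pseudoreplication by regressing community correlation on inter-point
    distance; builds sample correlation networks with maximum spanning
    trees, bipartite sample-OTU probability networks and combined
    mixed-model networks; computes culture-based alpha-diversity indices
    (Shannon, Pielou, Menhinick); and simulates realistic synthetic
    electropherograms and isolate tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
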