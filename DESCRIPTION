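Package: OntoSmiles
Title: Hierarchical Chemical Ontology Classification from SMILES
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Places novel chemical structures, given as SMILES strings, into
    the subsumption hierarchy of a chemical ontology such as ChEBI. Provides
    an OBO subsumption-graph container with transitive-closure, label-class
    selection and path-counting operations; ontology-derived multi-label
    dataset construction with cross-version test-set alignment; a chemically
    aware SMILES tokenizer; class-balanced effective-number loss weighting; a
    from-scratch Transformer encoder with a sigmoid multi-label head and
    attention-weight export; hierarchy-aware evaluation (datapoint-averaged
    and label-averaged F1, root-path and parent-distance specificity, and a
    four-way model-versus-model specificity comparison); and a seeded
    synthetic-ontology benchmark generator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Cheminformatics, Classification, Software
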