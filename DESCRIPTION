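Package: ChemLinker
Title: Similarity-Based Aggregation of Chemical and Biological Evidence for Query Compounds
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline engine that, given a query compound as a SMILES
    string, finds similar compounds across local chemical and biological
    tables using bound-pruned 166-bit structural-key Tanimoto search and
    12-moment ultrafast shape recognition (USR) descriptors, chains hits
    through bioassay descriptions, Gene Ontology terms and genes to
    diseases, and emits a six-section aggregate report (predictive models,
    active similars, chemogenomics, pathways, literature, inactive
    similars) as XML or JSON. Ships a seeded synthetic-store generator
    with planted relationship chains so the whole pipeline is testable
    without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, xml2, jsonlite
Suggests: testthat (>= 3.0.0), ChemmineR, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'fingerprint.R'
    'search2d.R'
    'shape3d.R'
    'config.R'
    'datastore.R'
    'annotate.R'
    'predictors.R'
    'aggregate.R'
    'serialize.R'
    'fixtures.R'
    'utils.R'
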