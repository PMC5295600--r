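Package: charrmap
Title: Linkage Mapping and Diploidization Analysis for Salmonid F1 Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds genetic linkage maps from outcrossed F1 family genotype
    tables using two-point LOD grouping, recombination-count (RECORD-style)
    marker ordering with adjacent double-crossover masking, and per-parent
    map distance estimation. Detects weak pseudolinkage between homeologous
    chromosome arms, classifies paralogous sequence variants (PSVs) left by
    the salmonid whole-genome duplication, and runs comparative
    chromosome-arm analyses of duplicate-locus and transposable-element
    distributions against a reference genome. Includes a synthetic F1-family
    simulator with residual tetrasomy and full ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'synthetic-family.R'
    'marker-qc.R'
    'linkage-grouping.R'
    'marker-ordering.R'
    'pseudolinkage.R'
    'homeology.R'
    'pipeline.R'
    'data-access.R'
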