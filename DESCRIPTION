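Package: neomsn
Title: Morphometric Similarity Networks of the Developing Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and analysis of morphometric similarity networks
    (MSNs) from multi-feature regional cortical profiles. Provides
    per-subject and group network construction from z-scored feature
    tables, classical single-feature structural covariance networks,
    affinity-propagation clustering (free and fixed cluster counts via
    preference bisection), bootstrap stability and per-subject clustering
    consistency, partition comparison by variation of information, its
    normalized form, Dice overlap and a spherical spin-permutation test,
    and nonparametric age and sex association statistics for edges, nodes,
    modules and single features with Benjamini-Hochberg and Storey pFDR
    multiple-testing control. A synthetic-cohort generator emulating a
    term-born neonatal imaging cohort (planted modules, age gradients, sex
    effects on a spherical parcellation) supports fully reproducible
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'stats.R'
    'analyses.R'
    'apcluster.R'
    'compare.R'
    'io.R'
    'msn.R'
    'neomsn-package.R'
    'pipeline.R'
    'syndata.R'
    'utils.R'
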