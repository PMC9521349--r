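Package: comutnet
Title: Co-Mutation Networks from Liquid-Biopsy Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of co-occurring pathogenic gene alterations in
    cell-free DNA comprehensive genomic profiling cohorts. Reads
    alteration-call tables, applies pathogenicity filtering, and builds
    binary patient-by-gene mutation matrices. Screens anchor genes (such as
    BRCA1 and BRCA2) for pairwise co-mutation and mutual exclusivity by
    Fisher's exact test with Benjamini-Hochberg false-discovery-rate
    control, then models multi-gene interdependence with discrete Bayesian
    networks: approximate neighbor discovery by score-based hill climbing,
    globally optimal structure search by A* over the order lattice with
    BDeu or BIC scoring, Dirichlet-smoothed parameter fitting, exact
    variable-elimination inference and loopy belief propagation, and
    conditional relative-risk-of-co-segregation queries. A synthetic-cohort
    generator with a planted dependency structure supports end-to-end
    validation when clinical data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
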