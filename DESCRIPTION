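Package: spcprof
Title: Spectral-Count Proteome Profiling and Differential Analysis
Version: 0.1.0
Authors@R:
    person("Paolo", "Verga", email = "paolo.verga@example.org", role = c("aut", "cre"))
Description: Label-free quantitative proteomics from spectral counts
    (MudPIT-style shotgun experiments). Reads per-run protein
    identification lists and PSM tables, assembles a protein-by-run
    spectral-count matrix, applies identification quality filters with
    target-decoy FDR estimation and replicate repeatability regression,
    profiles cohorts (average spectral counts, Venn partitioning,
    virtual 2D MW/pI maps, subcellular-location summaries), calls
    differentially expressed proteins with the DAve/DCI dual-index
    rule, selects discriminant proteins by per-protein F statistics
    with Mahalanobis cohort assignment and hierarchical clustering,
    and maps protein sets onto a protein-protein interaction network
    with hypergeometric term enrichment. Includes a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
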