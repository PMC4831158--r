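Package: acropipe
Title: Genotyping-by-Sequencing Population Genomics for Reef Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for reduced-representation (GBS) SNP panels in
    clonal reef corals and similar systems: barcode demultiplexing with
    restriction cut-site checks, a dual-caller SNP quality-control cascade
    (caller consensus, depth masking, iterative call-rate filtering, minor
    allele frequency, heterozygote-excess and linkage-disequilibrium pruning),
    within-population diversity via pairwise SNP differences with tag-length
    adjustment, Weir-Cockerham fixation indices with permutation tests,
    hierarchical analysis of molecular variance, FDIST-style outlier
    detection under a Balding-Nichols island model, and Mantel tests of
    isolation by distance. Includes a fully parameterised genotype simulator
    with recorded ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
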