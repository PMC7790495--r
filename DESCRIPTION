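Package: combEpi
Title: Fitness and Epistasis Inference from Combinatorial Mutant
    Library Enrichment Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of combinatorial site-directed mutant libraries
    under selection, as used to dissect the fitness landscape of the
    integron integrase IntI1. Long amplicon reads are curated
    (alignment, indel correction) into fixed-length residue strings
    (allele-IDs) over a panel of focal loci; marginal fitness of
    single mutations and mutation pairs is estimated from enrichment
    count ratios; pairwise epistasis is scored against a Poisson
    resampling null model of the selection-sequencing experiment.
    Degenerate-codon library design (e.g. GRM/RRT codons), plate-assay
    fold-change analysis with delta-method error propagation, and a
    ground-truthed synthetic data generator for end-to-end validation
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
biocViews: Sequencing, Genetics, Epistasis, ExperimentalDesign,
    StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
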