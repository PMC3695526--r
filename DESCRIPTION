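Package: sortseqmap
Title: Functional Mapping of Regulatory Sequences by Sort-Seq Saturation Mutagenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for saturation-mutagenesis sort-seq experiments, in
    which an error-prone-PCR mutant library of a short regulatory sequence is
    phenotypically fractionated by fluorescence-activated cell sorting and the
    sorted pools are deep sequenced. Provides experiment-design calculators
    (mutant-library coverage simulation, phred-score read-accuracy arithmetic),
    a full sort-seq simulator for generating synthetic paired-end data with
    known ground truth, paired-end read merging and exact-length filtering,
    exhaustive single-mutation counting against the reference amplicon,
    negative-binomial exact tests for over- and under-represented mutations
    between sorted conditions with median-of-ratios normalization and
    Benjamini-Hochberg correction, and hierarchical clustering of per-sample
    mutation patterns with Newick export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap
Config/testthat/edition: 3
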