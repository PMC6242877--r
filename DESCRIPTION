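Package: mirevol
Title: Comparative Evolution of microRNA Repertoires Across Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of microRNA gene evolution from
    small-RNA evidence: curation of hairpin loci (secondary-structure and
    arm-duplex read filters), greedy identity clustering of loci into
    orthogroups with synteny-supported presence calls, Dollo-parsimony
    reconstruction of gains and losses on a dated species tree with net
    gain rates per million years, classification of genomic origins
    (repeat-derived loci via a shuffle-null bit-score threshold, antisense
    couples, miRtrons, duplications, genomic context), tissue-specificity
    statistics, and seed-match target-site discovery with binned
    conservation profiles around sites. A synthetic-data module generates
    every input with known ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    ape,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
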