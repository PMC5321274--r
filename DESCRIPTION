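Package: paleodup
Title: Detection and Dating of Ancient Whole-Genome Duplications from
    Transcriptome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to detect and date ancient whole-genome duplication
    (WGD) events from assembled transcriptomes of closely related species.
    Implements best-match identification of paralog and ortholog gene
    pairs from similarity hits, NG86 estimation of synonymous (Ks) and
    nonsynonymous (Ka) substitution rates from gap-free codon alignments,
    per-species synonymous-clock calibration against dated outgroup nodes,
    Gaussian mixture modelling of Ks and age distributions with BIC model
    selection, Ka/Ks profiling through time, likelihood-based placement of
    WGD events on a dated species tree using gene-count birth-death models
    with retention rates, and a topology screen for duplication nodes in
    dated gene trees.  A synthetic-data module generates transcripts,
    paralog/ortholog Ks samples, codon pairs, gene-count matrices and
    dated gene trees with planted WGD signal so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
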