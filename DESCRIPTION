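Package: rdnafrag
Title: Detection of Additional Internal Transcribed Spacers and 28S rRNA
    Fragmentation in Nuclear rDNA Operons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-guided detection of additional internal transcribed
    spacers (ITSs) in nuclear rRNA operons, the cause of the fragmented mature
    28S rRNA ("hidden breaks") of euglenids and kinetoplastids. Locates rDNA
    contigs in genome assemblies by seed-and-extend homology search with
    Karlin-Altschul E-values and a multi-copy coverage filter, annotates
    18S-ITS1-5.8S-ITS2-28S segments, projects conserved helix anchors through a
    structure-aware multiple alignment, flags inter-helix expansions that are
    more than four-fold longer than in background species, classifies them as
    known additional ITSs, novel candidates, or SSU expansion segments, and
    tests whether shared ITS sites can be traced to a single ancestral gain by
    binary-character parsimony on a supplied phylogeny. A tree-based operon
    simulator with planted ITSs and high-coverage rDNA contigs provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
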