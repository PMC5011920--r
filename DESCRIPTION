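Package: histannot
Title: Annotation of Histone Gene Complements from Genomic Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating the histone gene complement of a genome:
    family and variant classification of histone proteins by global-alignment
    scoring against bundled references plus diagnostic residues (H3.3 sites,
    the H2A.X C-terminal SQ motif, macroH2A length), detection of the
    regulatory hallmarks of replication-dependent histone genes (upstream
    TATA-box, 3'-UTR stem-loop, purine-rich histone downstream element,
    polyadenylation signal) with rule-based replication-dependency and
    pseudogene calls, SPKK/SPKR sperm-histone motif counting and a protamine
    screen, tandem-cluster copy-number estimation from k-mer depth
    histograms, alignment-free k-mer distances with hierarchical clustering
    of stem-loop elements, and a synthetic-genome generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
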