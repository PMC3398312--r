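Package: crossprofiler
Title: Cross Profile Analysis of Protein Segment Structure and Sequence
    Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds structure-based amino-acid propensity profiles from
    dihedral-angle clusters of fixed-length protein backbone segments,
    searches them against libraries of sequence-based profiles (PSSMs)
    with a correlation-scored global-local aligner and log-length
    corrected Z-scores, quantifies sequence evolution toward or away
    from a structural motif via compatibility scores S and score
    differences to an ancestral sequence, and embeds segment sequence
    families into a two-dimensional evolutionary landscape by classical
    scaling of Hamming dissimilarities. Includes seeded synthetic-data
    generators (backbones from dihedral angles, planted segment
    clusters, mutated sequence families, decoy PSSM libraries) so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    interp,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
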