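Package: selnest
Title: Detection and Classification of tRNA-Sec Genes Nested in selB Open
    Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates bacterial selenocysteine tRNA (tRNA-Sec, selC) gene
    sequences that lie inside, partially overlap, or are reverse-complement
    embedded in selB elongation-factor open reading frames; classifies each
    locus into one of the recurring overlap archetypes (complete forward
    nested with stop-start translational coupling, adjacent, long-spacer
    separated, 5'-half remnant, partial overlap with the stop codon inside
    the tRNA, complete reverse-complement nested); extracts tRNA gene
    features (length, encoded CCA tail, discriminator base); derives the
    conceptually translated C-terminal extension signatures of the host
    ORFs and a tRNA-coordinate-anchored conservation profile; and scans for
    a sigma-70-like selC promoter near the selB stop codon. Ships a
    deterministic synthetic-genome simulator that plants each archetype
    with ground-truth labels, plus end-to-end scan and evaluation
    functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
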