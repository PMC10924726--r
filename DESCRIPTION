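Package: paralogid
Title: Discriminating Coding Paralogues with Proteomic Peptide Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides which member of a family of near-identical paralogous
    genes produces the observed protein. Implements in-silico tryptic
    digestion with missed-cleavage accounting, quality filtering and mapping
    of peptide-evidence tables onto candidate paralogue sequences,
    unique-peptide attribution with observation weighting, rescue of
    unmapped peptides as single amino acid variants, cross-species
    conservation profiling of paralogue-specific substitutions and indels,
    transcript coding-status assessment (premature stops, frameshifts,
    5'-truncations), and a TN93 + neighbor-joining distance analysis of the
    family. A seeded synthetic-data generator produces paralogue families,
    orthologue alignments, haplotype panels and peptide-evidence tables
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
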