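Package: ddgpred
Title: Untrained Sequence- and Structure-Based Prediction of Protein
    Stability Change upon Amino-Acid Substitution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the change in protein unfolding free energy
    (delta-delta-G, kcal/mol) caused by single and multiple amino-acid
    substitutions, using only fixed, untrained ingredients: a per-position
    amino-acid frequency profile built from a multiple sequence alignment,
    the BLOSUM62 substitution matrix, a sequence-window pairwise contact
    potential, the Kyte-Doolittle hydropathy scale, and - when a structure
    is supplied - a spatial-contact potential over the 5 Angstrom
    environment of the variant site modulated by relative solvent
    accessibility. All single-site scores are anti-symmetric by
    construction, so a substitution and its reverse receive opposite
    predictions. Multi-site variants are combined with a max + min - mean
    rule. Includes readers for aligned FASTA/A3M alignments and PDB chains,
    a synthetic-fixture generator for alignments and toy structures, a
    numeric solvent-accessibility routine, plotting helpers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
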