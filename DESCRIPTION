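Package: tagsite
Title: Scoring Protein Positions for Non-Disruptive Epitope Tag Insertion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts amino-acid positions where an epitope tag (such as V5
    or ALFA) can be inserted into a protein with minimal risk of disrupting
    its function. Four per-residue feature tracks are combined: sequence
    conservation (Shannon entropy of multiple-sequence-alignment columns,
    normalized by log2(20)), secondary structure (DSSP codes binned by
    expected sensitivity to insertion), relative solvent accessibility
    (SASA over the residue's theoretical maximum), and the complement of a
    disordered-binding-region probability (ANCHOR2-style track). A weighted
    sum score and an unweighted minimum score are computed per position;
    the minimum score, averaged over a sliding window, is used to rank
    candidate insertion sites. Includes parsers for aligned FASTA, classic
    DSSP output, BLAST tabular hit lists and IUPred2A/ANCHOR2 text output,
    a deterministic Shrake-Rupley solvent-accessibility fallback, report
    writers (per-residue TSV, ranked-site TSV, protein-coordinate BED), a
    synthetic fixture generator for end-to-end offline testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
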