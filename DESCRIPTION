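Package: asoscreen
Title: Off-Target Annealing and Splice-Switching Analysis for Antisense
    Oligonucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and quantifying hybridization-dependent
    off-target effects of splice-switching antisense oligonucleotides (ASOs).
    Implements a mismatch-, wobble- and bulge-tolerant semi-global duplex
    aligner for scanning ASOs against pre-mRNA sequence, chemistry-specific
    competence rules for 2'-O-methoxyethyl (MOE), 2'-O-methyl (OMe) and
    morpholino (PMO) ASOs, percent-spliced-in (PSI) event filtering on
    junction-count tables, gel densitometry percent inclusion, delta-delta-Ct
    relative expression, and differential-expression table summaries, together
    with a synthetic-data generator producing transcripts with planted target
    sites, event tables with planted splicing effects, and qPCR tables with
    planted fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
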