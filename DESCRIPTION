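Package: cas13sg
Title: Structure-Guided Cas13 Guide RNA Design and Cleavage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing Cas13 (crRNA) guides against the
    single-stranded regions of a target transcript and for quantifying
    Cas13-mediated cleavage from aligned reads. Reads RNA secondary
    structures (connectivity tables, extended dot-bracket with pseudoknot
    alphabets) and structure-probing score tracks (PARS convention),
    segments transcripts into single-stranded/double-stranded regions and
    junctions, flags pseudoknotted (crossing) base pairs, enumerates and
    ranks spacer candidates by single-strand complementarity with an
    8-base central-seed rule, annotates protospacer flanking sites, screens
    spacers for self-complementarity and dimer propensity, and computes
    per-region cleavage rates from treatment-versus-control coverage with a
    rank-sum comparison of single- versus double-stranded regions. Includes
    a deterministic synthetic-data generator (structured transcripts,
    probing tracks, read sets with planted cleavage) for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
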