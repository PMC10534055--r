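Package: nmdescape
Title: Annotate Premature Termination Codon Variants for Predicted Escape
    from Nonsense-Mediated mRNA Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates variants that generate premature termination codons
    (PTCs) with predicted escape from nonsense-mediated mRNA decay (NMD).
    For every PTC-generating variant-transcript pair the location of the
    5'-most novel stop codon in the reconstructed mutant coding sequence is
    determined, and five experimentally motivated escape rules (last coding
    exon, within 50 bp of the penultimate exon junction, within 150 bp of
    the coding start site, exon longer than 407 bp, intronless transcript)
    are evaluated and reported individually. All PTC-causing variant
    classes are handled - single-nucleotide variants, insertions,
    deletions and insertion-deletions, including frameshifts whose PTC
    arises downstream of the variant site - with explicit reconstruction
    of the mutant coding sequence so that inserted sequence content is
    taken into account. Includes VCF input/output with INFO-field
    annotation, variant left-normalization, a precomputed index of all
    stop-gain SNVs for a transcript set, a synthetic genome/annotation/
    variant fixture generator, and an independent brute-force annotation
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    ggplot2,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
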