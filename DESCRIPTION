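Package: mitocode
Title: Assessment of Alternative Mitochondrial Genetic Codes from Coding-Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess which mitochondrial genetic code a lineage uses
    from protein alignments of mitochondrial genes such as Cox1 and Cob.
    Provides frozen NCBI-style translation tables (standard, vertebrate,
    invertebrate, echinoderm and ascidian mitochondrial codes), translation
    and stop-codon scanning under alternative codes, extraction of gene
    regions from contigs with GenBank-style bracket coordinates, majority
    consensus and haplotype grouping for EST-like fragment sets, threading of
    codons onto a protein multiple sequence alignment, conserved-column codon
    usage tables with a configurable mismatch-tolerant conservation rule,
    counting-based inference of candidate codon reassignments with a
    small-parsimony note on a phylogeny, and a seeded simulator of
    indel-free coding-gene families with lineage-specific codes for
    end-to-end validation against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
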