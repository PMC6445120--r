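Package: genomepair
Title: Comparative Analysis of Paired Genome Assemblies and LTR Retrotransposon Dynamics
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computations used when comparing two
    chromosome-scale assemblies of closely related genotypes: assembly QC
    scans (telomere arrays, heterochromatin windows, gap-aware contig N50),
    reciprocal gap closure by flank anchoring, validation and classification
    of structural and presence/absence variation, cross-genome classification
    and molecular dating of intact LTR retrotransposons (target-site
    duplications, LTR-LTR divergence, cumulative nucleotide substitution
    rates), and presence/absence marker co-segregation with in-silico PCR.
    Includes a seeded synthetic genome-pair simulator with a complete truth
    ledger so every stage is testable against known events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
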