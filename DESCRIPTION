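Package: scentvar
Title: Floral Volatile Profiles and Monoterpene Synthase Sequence Variation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Links floral volatile emission profiles to coding-sequence
    variation in monoterpene synthase (TPS) genes. Provides internal-standard
    GC-MS quantification and rule-based aroma-type classification of cultivar
    volatile profiles; SNP and InDel calling on panels of near-identical cDNA
    open reading frames with coding-effect annotation, isoform grouping and
    terpene-synthase motif scanning (RRX8W, RX8W, DDXXD, NSE/DTE); nucleotide
    diversity (pi) and haplotype diversity (Hd) estimation; spliced alignment
    of cDNA isoforms onto a genomic locus with GT-AG validation and
    alternative 5'/3' splice-site classification; and gray relational analysis
    associating polymorphic sites with volatile emissions. A synthetic-data
    generator produces gene models, splice isoforms, haplotype panels and
    emission tables with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
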