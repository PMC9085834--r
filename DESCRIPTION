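Package: snpcoloc
Title: Colocalization Enrichment of GWAS Variants with Regulatory Region Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-set colocalization analysis linking GWAS variant positions
    to collections of regulatory DNA regions and DNA binding regions (DBRs) of
    molecular transducers. Implements LOLA-style 2x2 contingency construction
    against a background universe, one-sided Fisher's exact enrichment tests
    with Benjamini-Hochberg false-discovery control, a harmonic-mean composite
    ranking score, multi-transducer hotspot (Venn) intersection, joining of
    hotspots to precomputed Activity-By-Contact enhancer-gene predictions, and
    accumulative hypergeometric gene-set enrichment. Ships a synthetic-data
    generator with planted enrichment so the full pipeline runs and is
    testable without external downloads, and a command-line interface covering
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
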