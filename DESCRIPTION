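Package: gRNAdesign
Title: Guide RNA Design for the CRISPR/Cas9 System with Off-Target,
    Variant, Structure and AT-Content Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers candidate CRISPR/Cas9 targets matching the N20-NGG
    protospacer/PAM pattern in query sequences, maps each 23-bp target back
    to a reference genome allowing at most one mismatch via a pigeonhole
    k-mer index (checking mapping uniqueness), annotates overlapping SNPs
    and indels from a VCF with strand-aware distances to the target's 3'
    end, folds the full guide RNA (guide plus tracrRNA-fusion scaffold) by
    base-pair maximization to count guide bases sequestered by secondary
    structure, computes AT content, and ranks candidates for TSV or HTML
    reporting. Includes seeded fixture generators producing toy genomes and
    VCFs with known ground truth, and a bundled set of published human
    guides for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
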