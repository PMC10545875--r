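Package: pgthap
Title: Haplotype-Based Preimplantation Genetic Testing for Monogenic Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for single-gene preimplantation genetic testing
    (PGT-M) by SNP haplotype linkage analysis. Phases parental haplotypes
    through a reference embryo by Mendelian deduction, anchors the risk
    haplotype to a known pathogenic variant, and diagnoses biopsied embryos
    under allele dropout with flank-wise voting and recombination detection.
    Companion stages call mosaic aneuploidy from low-pass binned read counts,
    predict the transmitted maternal haplotype from maternal plasma cfDNA by
    relative haplotype dosage with a sequential probability ratio test
    (NIPT-M), and verify splice effects by global alignment of transcripts
    with HGVS-coordinate deletion calls. A synthetic-family generator
    reproduces the statistical structure of chip genotypes, biopsy
    amplification noise, low-pass coverage, and plasma sequencing so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
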