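Package: utrscan
Title: Somatic Mutation Analysis of Untranslated Regions in Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for detecting and characterizing somatic
    mutations in the untranslated regions (UTRs) of cancer driver genes from
    targeted liquid-biopsy sequencing. Implements a five-condition somatic
    caller for plasma cell-free DNA pileups with a white-blood-cell cohort
    background-error model, a split-read anchor algorithm for large (up to
    500 bp) indels, coverage-normalized regional mutation-rate statistics,
    ctDNA-fraction-corrected clonality and longitudinal clone tracking,
    indel sequence-context and mechanism classification (tandem duplications
    and repeat-unit deletions), exact two-sided statistical tests, and an
    RPKM and androgen-receptor activity expression layer. A fully synthetic
    targeted-panel cfDNA cohort generator with a planted truth set makes
    every stage testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
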