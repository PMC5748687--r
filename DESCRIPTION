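Package: saltSRNA
Title: Small RNA, Degradome and tasiRNA Analysis for Plant Salt-Stress Libraries
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for two-condition plant small RNA-seq studies:
    adapter trimming and tag collapsing, structural-RNA annotation with a fixed
    priority rule, conserved miRNA matching against a known-miRNA reference,
    novel miRNA discovery by hairpin excision with miRNA* duplex evidence and
    minimal-folding-free-energy-index (MFEI) statistics, TPM normalisation with
    an exact two-library count test, siRNA duplex detection by the 2-nt 3'
    overhang rule with repeat mapping, degradome (PARE) cleavage-site calling
    with five-category classification and t-plot tables, and miR390/TAS3
    two-hit tasiRNA phasing with tasiRNA-ARF target prediction. Includes a
    seeded synthetic-data generator with full ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
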