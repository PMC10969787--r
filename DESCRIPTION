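Package: pgxkit
Title: Pharmacogenetic Star-Allele Calling and Clinical Decision Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tertiary analysis toolkit for NGS-based pharmacogenetic (PGx)
    testing. Filters per-sample VCF variant calls to a curated catalog of 13
    pharmacogenes, calls star-allele diplotypes from unphased genotype
    dosages, translates diplotypes to metabolizer phenotypes using CPIC-style
    rules (including the CYP2D6 activity-score system), and renders clinical
    decision-support reports in single-gene-drug, summary, and full formats.
    Includes a concordance harness for validating calls against truth sets
    and a seeded fixture generator that synthesizes VCFs for any catalog
    diplotype, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
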