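Package: satsplice
Title: Saturation Interpretation of Coding SNV Splicing Impact from
    SpliceAI Scores and Full-Length Gene Splicing Assay Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prospectively interpreting the splicing impact of
    every possible coding single-nucleotide variant (SNV) in a small
    multi-exon gene. Implements gene models with cDNA/pre-mRNA/genomic
    coordinate arithmetic on either strand, saturation SNV enumeration
    with protein-consequence calling across exon junctions, ingestion of
    SpliceAI delta-score tables with offset resolution and a
    physiological-relevance filter for loss scores, rule-based selection
    of assay candidates, modelling of full-length gene splicing assay
    (FLGSA) outcomes with densitometric aberrant/normal ratios,
    sensitivity/specificity cutoff calibration with extrapolation to
    untested variants, 5' splice-donor signal scoring against the U1
    snRNA 5' end, and a synthetic-data generator emulating all inputs.
    Ships score/outcome fixtures for the four-exon SPINK1 gene.
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
    jsonlite
Config/testthat/edition: 3
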