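Package: mitovar
Title: Mitochondrial Genome Characterization for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the mitochondrial genome in tumor
    cohorts: variant calling of whole-mtDNA sample sequences against a
    circular 16,569-bp reference, consequence and conservation annotation
    under the vertebrate mitochondrial genetic code, a rule-based
    pathogenicity classifier combining frequency/conservation filters with
    a seven-predictor majority vote, haplogroup assignment from a tree of
    defining variants, relative mtDNA copy number from qPCR Ct tables, and
    case-control association statistics.  A synthetic-cohort generator with
    recorded ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
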