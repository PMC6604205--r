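Package: pdxsoma
Title: Somatic Variant, Copy-Number and Expression Post-Processing for
    Patient-Derived Xenografts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing workflows for genomic data from patient-derived
    xenograft (PDX) tumors sequenced without a matched normal sample.
    Implements k-mer based separation of host (mouse) from graft (human)
    sequencing reads with paired-read retention rules and sample-level
    coverage gates; a tumor-only somatic filter-and-rescue engine combining
    GATK-style hard filters, depth and allele-fraction thresholds,
    database-driven germline subtraction, cohort-recurrence artifact
    filtering and clinical-knowledgebase rescue with a full per-variant
    audit trace; gene-level copy-number and loss-of-heterozygosity
    annotation from allele-specific segments with ploidy-relative gain and
    loss calling; an EBV-associated lymphoma classifier built on
    upper-quartile normalized expression z-scores; and precision/recall
    benchmarking plus cohort-concordance statistics. Seeded generators
    emulate every input (references, reads, variant cohorts, expression
    cohorts, copy-number profiles) so the complete pipeline is exercisable
    on synthetic data with planted truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Sequencing, SomaticMutation, CopyNumberVariation,
    GeneExpression, Classification
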