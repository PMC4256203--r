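Package: sialoseq
Title: Comparative Salivary-Gland Transcriptome Analysis for Triatomine RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative sialotranscriptome (salivary
    gland transcriptome) analysis of multi-library RNA-seq designs such as the
    Triatoma infestans nymph/adult by geographic-population study. Provides
    quality trimming and rejection of reads, exact k-mer seeded read counting
    onto coding sequences with a capped tied-match rule, RPKM quantification,
    normalized-ratio plus chi-squared differential-expression calls between
    developmental stages and populations, keyword-vocabulary functional
    classification, synonymous/non-synonymous SNP polymorphism statistics per
    functional class, rDNA haplotype collapsing and alignment-column
    summaries, and a fully deterministic synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
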