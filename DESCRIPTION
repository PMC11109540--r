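Package: snperr
Title: Simulated Genotyping Error Injection and Concordance Evaluation
    for VCF Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Probabilistically injects nine genotype error and missingness
    modes (heterozygous drop-out, homozygous drop-in, opposite-homozygous
    swaps, and per-class missingness) into a single designated sample of a
    multi-sample VCF, streaming record by record and leaving every other
    sample untouched. Includes a companion concordance evaluator computing
    per-class mismatch counts, the full truth-by-query genotype transition
    matrix, and non-reference concordance (NRC); Hardy-Weinberg founder and
    pedigree gene-dropping simulators for generating test cohorts; and a
    KING-robust kinship benchmark measuring how relationship-degree
    inference degrades as a function of the kind and rate of genotyping
    error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rsamtools,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'genotype.R'
    'error-model.R'
    'vcf-io.R'
    'inject.R'
    'concordance.R'
    'synthetic.R'
    'kinship.R'
    'cli.R'
    'snperr-package.R'
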