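Package: clonecompare
Title: Whole-Genome Identity Analysis of Cloned and Donor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the genomic identity of a clone produced by
    somatic cell nuclear transfer (SCNT) against its nuclear donor from
    paired whole-genome sequencing. Implements raw-read quality filtering,
    PCR-duplicate removal, a simplified biallelic genotype caller, paired
    somatic subtraction with a Fisher exact allele-count filter, somatic
    mutation rates over the callable (depth 5-200) region, substitution
    spectra, case/control read-depth CNV segmentation with a BIC penalty,
    discordant-read-pair structural variant calling, and sequencing-based
    relative telomere length estimation from telomeric repeat content.
    Includes a paired-end read simulator that plants germline and somatic
    variants, copy-number and structural events, a replaced mitochondrial
    haplotype and telomeric tracts, providing truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    stringi,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
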