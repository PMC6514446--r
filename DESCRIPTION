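Package: polydosage
Title: Allele Dosage, Expression and Divergence Analysis for Polyploid Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for dissecting allele interactions at highly polyploid loci
    from haplotype-resolved genomic sequence and transcriptome reads. Catalogues
    variants among aligned locus haplotypes (SNPs, multi-base substitutions,
    indels), classifies allele-specific expression under a strict 100%-identity
    read-assignment rule, and tests missing-haplotype dosage hypotheses with an
    exact two-sided binomial test of transcriptome allele counts against genomic
    proportions v/P. Also provides model-corrected pairwise distances (JC69,
    K2P, Nei-Gojobori dS/dN), molecular-clock divergence dating (T = d/2r),
    LTR retrotransposon insertion ages, neighbor-joining phylogenies with
    outgroup rooting and monophyly tests, and a seeded synthetic-data generator
    for polyploid loci, duplications, LTR pairs and allele-specific read sets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
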