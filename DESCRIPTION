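Package: csmartnipt
Title: Noninvasive Prenatal Genotyping of Recessive Single-Gene Disorders
    from Single-Molecule Cell-Free DNA Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for noninvasive prenatal testing (NIPT) of
    autosomal-recessive single-gene disorders from barcoded, targeted
    cell-free DNA sequencing of maternal plasma, modelled on circulating
    single-molecule amplification and re-sequencing (cSMART) assays for
    MMACHC (cblC-type methylmalonic acidemia). Collapses PCR-duplicated
    barcoded reads into unique molecules, estimates the fetal DNA fraction
    from heterozygous SNP allele fractions, deduces maternal-fetal
    genotypes at each targeted locus by binomial maximum likelihood over
    five hypotheses with quality-control gating, combines per-locus calls
    into a clinical fetal status per pregnancy, and summarises concordance,
    sensitivity and specificity against invasive prenatal diagnosis with
    exact Clopper-Pearson confidence intervals. Includes a seeded synthetic
    cfDNA generator emulating carrier-couple trios, plasma mixtures,
    molecular-barcode duplication and per-read base error, so the whole
    pipeline is testable end-to-end without access-restricted patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
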