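Package: lohscar
Title: Locus-Specific Loss of Heterozygosity and Genomic Scar Scores in
    BRCA1/BRCA2 Carrier Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls BRCA1/BRCA2 locus-specific loss of heterozygosity (LOH)
    in tumor/normal pairs from allele-specific copy number segments and
    allele read counts, with purity-corrected allele-fraction evidence and
    an explicit mechanism taxonomy (LOH with deletion, copy-neutral LOH,
    LOH in gain, absent LOH, absent LOH with somatic second hit). Computes
    exome-based homologous-recombination-deficiency scar scores
    (telomeric allelic imbalance, large-scale state transitions with
    ploidy correction, genomic LOH) from Sequenza-dialect segment tables,
    implements carrier and somatic-variant eligibility filters,
    mutational burden, artifact-signature exclusion and PTEN
    extrapolation rules, and provides the group-comparison and survival
    statistics (Grubbs screen, pooled t-test, Fisher exact, ANOVA/Tukey,
    Kaplan-Meier/log-rank, Cox) used to relate LOH status to genomic and
    clinical endpoints. A synthetic tumor-cohort generator with known
    ground truth makes every stage testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
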