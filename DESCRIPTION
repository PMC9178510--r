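Package: ammscreen
Title: Automated Meiotic Mapping of Modifier Screens with Censored Onset Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of ENU-mutagenesis modifier screens in which
    pedigrees of mice are genotyped at induced coding/splice mutations and
    phenotyped for a censored time-to-onset trait (e.g. age of diabetes onset in
    NOD mice, monitored weekly and right-censored at 40 weeks). Provides a
    pedigree and phenotype simulator reproducing the G0 x WT -> G1, G1 x WT -> G2,
    G2 x G1-sire backcross breeding scheme; per-mutation single-locus linkage
    scans relating zygosity to onset age under recessive, additive and dominant
    inheritance models via Weibull proportional-hazards likelihood-ratio tests
    (with an optional dam-level frailty term) and Bonferroni correction;
    Kaplan-Meier and logrank utilities; candidate calling under count and
    significance criteria; and genome-saturation / genomic-footprint estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
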