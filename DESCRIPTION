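Package: EvoCohort
Title: Somatic Evolution and Cohort Genomics for Whole-Genome Tumour Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cohort-scale analysis of tumour whole-genome sequencing data,
    built around the mutational-clock timing of copy-number gains and
    whole-genome duplication. Estimates mutation multiplicity and cancer
    cell fraction from read counts, purity and allele-specific copy number;
    times gains in molecular time and converts to years before sampling
    under a two-phase clock; orders driver events across a cohort with a
    Bradley-Terry league model; tests driver co-occurrence and mutual
    exclusivity; detects structural-variant breakpoint hotspots against a
    covariate-adjusted negative-binomial background with permutation FDR
    and fragile-site filtering; computes genome-instability indices (WGD,
    wGII, TMB, arm-level recurrence); tests non-coding element burden with
    trinucleotide-context adjustment and Empirical Brown combination;
    classifies genetic immune escape from HLA and antigen-presentation
    alterations; and runs clinico-genomic survival analysis. A synthetic
    cohort generator with planted ground truth supports calibration and
    power analysis of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    survival,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
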