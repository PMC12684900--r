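Package: canroh
Title: Benchmarking Genotype Imputation and Runs-of-Homozygosity Inference
    for Ancient Canid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven benchmarking machinery for low-coverage genotype
    imputation and downstream inbreeding inference in dogs and wolves.
    Generates synthetic reference-panel allele frequencies, truth genomes with
    planted autozygous tracts, imputation-like noisy call sets with calibrated
    INFO scores, and pseudohaploid calls; quantifies imputation accuracy
    (MAF-binned squared correlation, per-genotype-class error rates,
    non-reference discordance) under INFO-score cutoffs; calls runs of
    homozygosity (ROH) with a sliding-window scan and estimates the genomic
    inbreeding coefficient F_ROH with a short/long partition; scores called
    ROH against truth tracts at base-pair and segment resolution (F1, MCC,
    sensitivity, specificity, FDR); maps windowed ROH prevalence across
    cohorts, detects ROH deserts, and assesses desert sharing with a
    randomization test; and evaluates PCA placement of partially observed
    samples via least-squares projection and eigenvalue-weighted PC distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    vcfR,
    jsonlite,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
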