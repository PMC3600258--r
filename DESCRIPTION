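Package: tpmtqpcr
Title: Allele-Specific Real-Time PCR Genotyping of TPMT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for allele-specific duplex real-time PCR genotyping of
    thiopurine S-methyltransferase (TPMT) star alleles. Computes threshold
    cycles (Ct) from raw amplification curves, applies internal-positive-
    control quality gating and delta-Ct threshold genotype calling per SNP,
    composes unphased genotypes into star-allele diplotypes with
    prior-based phase-ambiguity resolution and metabolizer phenotype
    prediction, and reports assay validation statistics (allele
    frequencies with exact confidence intervals, concordance against a
    reference method, Hardy-Weinberg exact tests). Includes a calibrated
    generative simulator of the duplex assay (amplification curves,
    internal controls, limit-of-detection dilution series) so the whole
    pipeline is testable without instrument data, and a command-line
    interface for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
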