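Package: multimine
Title: Multi-Mining of DNA and RNA Variation in Multiparent Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Candidate-gene discovery by combined allele mining and
    transcriptome mining in multiparent (MAGIC) populations. Parses
    SnpEff-annotated VCF files and applies quality, impact and
    homozygous-alternative-allele filters; screens population-scale
    expression matrices for bimodal (high-dispersion) genes using a
    decile-based percent-standard-deviation statistic; builds
    identity-by-state distance matrices and UPGMA trees over genomic
    intervals; tests two-locus additive epistasis on phenotypes by
    two-way ANOVA with contrasts against the best genotype class; and
    integrates the evidence streams into a ranked candidate table. A
    synthetic MAGIC recombinant-inbred-line data generator (founder
    haplotype mosaics, eQTL-driven bimodal expression, a two-locus
    additive phenotype) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    car
Config/testthat/edition: 3
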