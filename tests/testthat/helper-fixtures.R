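# small shared fixtures, all generated in code

small_config <- function(seed = 11, ...) {
  sim_config(n_rils = 60, loci_per_chromosome = 40, n_genes = 120,
             n_family = 30, seed = seed, ...)
}

# handcrafted 4-record, 3-sample SnpEff-style VCF for parser edge cases
write_tiny_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    # high-qual MODERATE record, phased hom-alt in s3
    paste("chr01", "100", ".", "A", "G", "600.0", "PASS",
          "ANN=G|missense_variant|MODERATE|geneX|geneX|transcript",
          "GT", "0/0", "0/1", "1|1", sep = "\t"),
    # boundary qual 500, MODIFIER only
    paste("chr01", "200", ".", "C", "T", "500.0", "PASS",
          "ANN=T|intergenic_region|MODIFIER|geneY|geneY|transcript",
          "GT", "0/0", "0/0", "0/1", sep = "\t"),
    # no ANN key, missing and multiallelic genotypes
    paste("chr02", "150", ".", "G", "A,T", "900.5", "PASS", ".",
          "GT", "./.", "1/2", "2/2", sep = "\t"),
    # two annotations (second one for geneX again), low qual
    paste("chr02", "300", ".", "T", "C", "100.0", "PASS",
          paste0("ANN=C|stop_gained|HIGH|geneZ|geneZ|transcript,",
                 "C|missense_variant|MODERATE|geneX|geneX|transcript"),
          "GT", "1/1", "0/0", "0/0", sep = "\t"))
  writeLines(lines, path)
  path
}
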