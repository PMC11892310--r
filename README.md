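# multimine

Candidate-gene discovery by combined **allele mining** and **transcriptome
mining** in multiparent (MAGIC) populations, with two-locus epistasis
testing, region phylogenies and multi-evidence integration. The package is
aimed at plant quantitative geneticists who have (a) a SnpEff-annotated VCF
for a diversity panel and (b) population-scale expression and phenotype data
for a recombinant-inbred-line (RIL) population, and who want to triangulate
which genes under their QTL are worth validating.

## What it computes

**Allele mining.** Variants are kept when QUAL > 500, at least one SnpEff
annotation is HIGH or MODERATE impact, and at least one line is homozygous
for the alternative allele (`1/1`); the surviving records are reduced to the
set of affected genes.

**Transcriptome mining.** For each gene, expression (RPKM) across the n RILs
is summarized by its decile means — p10, the mean of the ⌊n/10⌋ smallest
values, and p90, the mean of the ⌊n/10⌋ largest — and the percent standard
deviation

    pcSD = 100 · (p90 − p10) / (p90 + p10)  ∈ [0, 100].

Genes with pcSD > 45 and p90 > 3 RPKM are flagged bimodal: a segregating
expression QTL splits the population into a low and a high mode and drives
pcSD toward 100.

**Region phylogeny.** Identity-by-state distances (per-locus allele sharing:
identical homozygotes 1, het vs homozygote 0.5, opposite homozygotes 0) over
an interval's variants, clustered by UPGMA into a rooted ultrametric tree,
serialized as Newick, optionally oriented by an outgroup genotype vector.

**Two-locus epistasis.** RILs homozygous at two candidate loci are
stratified into the four REF/ALT classes; `value ~ A * D` is tested with
Type II sums of squares, and every class is contrasted against the
best-performing class by Welch t-tests. Under additivity the interaction
term is null while both main effects are recovered.

**Integration.** One row per gene with five evidence flags — DNA variant,
bimodal at 8 DPA, bimodal at 16 DPA, gene-family precedent, QTL overlap —
ranked by evidence count, then maximum pcSD.

A synthetic MAGIC generator (`simulate_magic()`: 11 founders, 550 RILs,
founder-haplotype mosaics, eQTL-driven bimodal expression, a two-locus
additive phenotype) provides ground-truthed datasets for every stage, so the
whole pipeline is testable without any external download.

## Worked example

```r
library(multimine)

sim   <- simulate_magic(sim_config(seed = 1))     # 550 RILs, 1,000 variants
paths <- write_dataset(sim, "magic_sim")

## allele mining
vs    <- read_snpeff_vcf(paths["vcf"])
chain <- filter_hom_alt(filter_impact(filter_quality(vs)))
chain
#> variant_set: 170 records, 550 samples
dna <- genes_affected(chain)                      # 156 affected genes

## transcriptome mining (both timepoints)
d8  <- dispersion_table(read_expression_tsv(paths["expr8"]))
d16 <- dispersion_table(read_expression_tsv(paths["expr16"]))
head(rank_by_pcsd(bimodal_filter(d8)), 3)
#>     gene_id       p10       p90     pcsd ... bimodal rank
#> 1 gene01343  5.559967  61.24568 83.35480 ...    TRUE    1
#> 2 gene00011 22.184442 244.34857 83.35333 ...    TRUE    2
#> 3 gene00539  2.473424  27.22268 83.34176 ...    TRUE    3

## two-locus epistasis at the designated driver loci
g  <- sim$genotypes; dr <- sim$panel$drivers
design <- stratify(setNames(g[, dr["A"]], rownames(g)),
                   setNames(g[, dr["D"]], rownames(g)), sim$phenotype)
epistasis_anova(design)
#> Two-locus additive epistasis ANOVA (n = 541 homozygous lines)
#>
#>       term     sum_sq  df          F         p
#>          A 464.160000   1 491.590000 8.067e-78
#>          D  81.333000   1  86.141000 4.104e-19
#>        A:D   0.049695   1   0.052633 8.186e-01
#>  Residuals 507.030000 537         NA        NA
#>
#> Genotype classes (A/D):
#>    class   n   mean     sd
#>  REF/REF 293 29.990 0.9818
#>  REF/ALT 103 30.847 0.8649
#>  ALT/REF 100 32.070 1.0200
#>  ALT/ALT  45 32.974 1.0270

## evidence integration
fam <- read.delim(paths["family"])$gene_id
tab <- annotate_candidates(dna, d8, d16, family_list = fam,
                           gene_coords = read.delim(paths["coords"]),
                           qtl_intervals = read.delim(paths["qtl"]))
print(tab, n = 3)
#> Candidate table: 2000 genes; top 3 rows:
#>    gene_id has_dna_variant ... in_family qtl_hits max_pcsd evidence_count rank
#>  gene01477            TRUE ...      TRUE   qD-STR    83.04              5    1
#>  gene00483            TRUE ...      TRUE   qA-STR    81.57              5    2
#>  gene01490           FALSE ...      TRUE   qD-STR    82.86              4    3
```

Reading the output: both main effects are highly significant while the
interaction p = 0.82 — the two loci act additively, the highest-strength
class being ALT/ALT (mean 32.97 vs 29.99 for REF/REF). The two top-ranked
candidates, `gene01477` and `gene00483`, are exactly the generator's
designated driver genes (`sim$genes$driver_genes`), each carrying all five
evidence flags.

A thin command-line front end over the same functions is installed at
`inst/cli/multimine.R` (subcommands `simulate`, `mine-variants`,
`mine-expression`, `tree`, `epistasis`, `integrate`).

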