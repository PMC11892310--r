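---
title: "Multi-mining methods: models, statistics and design choices"
author: "multimine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-mining methods: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimine)
```

# The problem

Cotton fiber quality and related end-use traits (strength STR, length UHML,
micronaire MIC, flammability) are controlled by alleles that segregate both
in historic germplasm and in structured breeding populations. `multimine`
implements a "multi-mining" strategy that triangulates candidate genes from
four independent evidence streams:

1. **Allele mining** — consequential DNA variants in a diversity panel,
   read from a SnpEff-annotated VCF;
2. **Transcriptome mining** — genes whose expression across a large
   multiparent (MAGIC) recombinant-inbred-line population is *bimodal*,
   the signature of a segregating expression QTL (eQTL);
3. **Phenotype genetics** — two-locus genotype stratification and
   additive-epistasis ANOVA linking candidate loci to a quantitative trait;
4. **Precedent** — membership in homology-derived gene families already
   implicated in the trait, and physical overlap with mapped QTL intervals.

Each stream is an exported module; `annotate_candidates()` combines them
into a ranked candidate table. Because the raw sequencing data such a study
rests on are rarely redistributable, the package ships a ground-truthed
synthetic MAGIC generator (`simulate_magic()`) so every stage is testable
end to end.

# Allele mining

A variant is retained when it passes three gates, applied in any order
(the filters commute):

* `filter_quality()` — phred-scaled call quality strictly greater than 500.
  Records with missing QUAL are excluded with a warning.
* `filter_impact()` — at least one SnpEff annotation with predicted impact
  HIGH or MODERATE. Matching is per record, any-match, mirroring a
  line-level `grep -E 'HIGH|MODERATE'` on the annotated VCF text.
* `filter_hom_alt()` — at least one sample homozygous for the alternative
  allele (`1/1`), i.e. the allele is actually fixed in some line rather
  than only observed in heterozygous state.

On multiallelic records a call is hom-ALT when both allele indices are
equal and non-zero (`2/2` counts), het when they differ. Both `/` and `|`
separators are accepted. `genes_affected()` reduces the surviving records
to the deduplicated set of annotated gene ids; `count_haplotypes()` groups
lines by complete marker vectors, with lines carrying missing calls
reported as unassigned rather than forced into (or allowed to inflate) the
haplotype count — a missing call could hide either allele, so exclusion is
the conservative choice.

# Transcriptome mining: the decile-dispersion statistic

Expression is normalized as RPKM,
$\mathrm{RPKM} = \dfrac{c}{(L/10^3)\,(N/10^6)}$
for count $c$, gene length $L$ bp and library size $N$. For each gene,
across the $n$ lines of the population:

* sort the values; the **lowest decile** is the $\lfloor n/10 \rfloor$
  smallest values (minimum 1), the **top decile** the same number of
  largest values;
* $p_{10}$ and $p_{90}$ are the decile means;
* the **percent standard deviation** is
  $\mathrm{pcSD} = 100\,\dfrac{p_{90}-p_{10}}{p_{90}+p_{10}}$,
  defined as 0 when both decile means are zero.

A gene is flagged bimodal when $\mathrm{pcSD} > 45$ **and** $p_{90} > 3$
RPKM (both strict, matching the "greater than 45%" / "> 3 RPKM" phrasing
of the thresholds). The second gate discards genes that are not actually
expressed in the tissue. With a strong biallelic eQTL the population
splits into a low and a high mode: the deciles sample the two modes,
$p_{90}/p_{10}$ approaches the allelic fold change, and pcSD is driven
toward its maximum of 100 (attained exactly when $p_{10}=0<p_{90}$; for
nonnegative data pcSD is always in $[0,100]$ and is invariant to
rescaling a gene's values).

**Why this definition.** "Percent standard deviation alongside decile
means" admits more than one formula, and two readings are defensible: (a) the population
SD of the two decile means expressed as a percentage of their mean — which
simplifies to $100\,(p_{90}-p_{10})/(p_{90}+p_{10})$ — and (b) a plain
percent coefficient of variation over all samples. We default to (a): it
is built from the same decile means the method already reports, it is
bounded in $[0,100]$ so a fixed 45 threshold is meaningful regardless of
scale, and it is much more specific to *bimodality* than a CV, which is
also inflated by unimodal long tails. Reading (b) remains available via
`dispersion_table(method = "cv")` for users who want to reproduce a
CV-based ranking.

Ties in `rank_by_pcsd()` break by descending $p_{90}$, then gene id, so
rankings are a deterministic total order. `year_effect_anova()` is a
one-way fixed-effects ANOVA computed directly from between/within sums of
squares (cross-checked against `aov` in the test suite); it is the guard
that planting-year environment does not masquerade as expression
variability.

# Region phylogeny

`ibs_distance()` computes pairwise identity-by-state distances over the
loci of a genomic interval. Per locus the similarity of two diploid dosage
calls is $1-|d_1-d_2|/2$: identical homozygotes 1, het vs homozygote 0.5,
opposite homozygotes 0, and het vs het 1 under the default unordered-pair
(multiset identity) convention. The exact het–het convention differs
between implementations; `het_het = 0.5` switches to the expected-sharing
convention. Loci with a missing call in either taxon are skipped for that
pair, and a pair with no comparable loci is an error naming the pair.
Distance is 1 minus the mean similarity over compared loci, so all
distances live in $[0,1]$.

`upgma()` is standard unweighted pair-group agglomeration: merge the
closest pair, set the node height to half the merge distance, and update
distances by the size-weighted mean (equivalently the unweighted mean over
member leaves). Exact distance ties are broken by the lexicographically
smallest pair of cluster labels (a cluster is labelled by its smallest
leaf), making output independent of taxon input order. The result is
hclust-compatible (so `stats::cophenetic()`, `plot()` and
`ape::as.phylo()` apply) and serializes to Newick via `to_newick()`, with
metacharacter-containing labels single-quoted. The test suite checks exact
cophenetic equivalence against `stats::hclust(method = "average")` and
`phangorn::upgma()` on thousands of random matrices, ultrametricity via
`ape`, and a hand-worked three-taxon example.

UPGMA trees are inherently rooted; `with_outgroup()` adds a reference
genotype vector (e.g. a sister-species reference sequence) as an extra
taxon so the root can be read against a known lineage. By default
`region_tree()` uses all interval variants passing the quality gate;
passing gene coordinates restricts it to gene-overlapping variants, which
is the appropriate choice when the interval is dominated by intergenic
repeats.

# Two-locus epistasis

`stratify()` reduces the population to lines homozygous at both candidate
loci — heterozygous or missing lines are excluded and counted, since with
~1% residual heterozygosity per locus the het classes are tiny and
uninterpretable in a RIL design — and keys them into the four classes
REF/REF, REF/ALT, ALT/REF, ALT/ALT.

`epistasis_anova()` fits `value ~ A * D` and reports **Type II sums of
squares** by model comparison ($SS_{A|D} = RSS(\sim D) - RSS(\sim A+D)$,
etc.), the appropriate choice for the heavily unbalanced cell counts of
RIL data where the ALT classes can be a small minority. On balanced
designs Type I and Type II coincide (asserted in the tests, which also
cross-check against `car::Anova`). Numerical edge cases are defined rather
than fatal: with a zero residual (noiseless input) the sums of squares are
exact and F/p are NA; with an empty cell the interaction is not estimable
and its row is NA while main effects come from the additive model. Under
the generative model used throughout
($y=\mu+\beta_A\,\mathbb{1}_{A}+\beta_D\,\mathbb{1}_{D}
+\beta_{AD}\,\mathbb{1}_{A}\mathbb{1}_{D}+\varepsilon$), additivity means
$\beta_{AD}=0$ and the interaction SS estimates pure noise.

`contrasts_vs_best()` compares every class to the best (highest-mean)
class by Welch two-sample t-tests, reporting the finest of the supplied
alpha levels passed (defaults 0.01 and 0.001, the levels used when
presenting this kind of result). Welch is preferred to pooled-variance or
Tukey HSD because class variances and sizes differ; no multiplicity
correction is applied beyond reporting fixed alpha levels, mirroring how
such contrasts are conventionally presented — users needing familywise
control should adjust the three p values themselves.
`genotype_expression_summary()` applies the same 2×2 machinery to
candidate-gene expression, checking that each gene's transcript tracks its
own locus with no significant effect of the other locus or the
combination.

# Candidate integration

`annotate_candidates()` builds one row per gene seen in any input.
`evidence_count` sums five discovery flags — DNA variant, bimodal at
8 DPA, bimodal at 16 DPA, family precedent, QTL overlap — and the table is
ranked by descending evidence count, then descending maximum pcSD, then
gene id. `fiber_expressed` (top-decile mean > 3 RPKM at either timepoint)
is reported as its own column but *not* counted: it is a component of the
bimodality gate, so counting it would double-weight expression evidence
and make "bimodal but unexpressed" impossible bookkeeping. Gene–QTL
overlap uses any-overlap semantics on 1-based inclusive coordinates (QTL
interval files here are 1-based inclusive, *not* BED half-open), with an
optional symmetric flank for "close to QTL" searches. The ranking itself
is this package's convention; the evidence flags, not the ordinal rank,
are the scientific output. `flammability_screen()` is the both-timepoints
intersection of the bimodal sets restricted to a supplied family list.

# The synthetic MAGIC generator

`simulate_magic()` emulates the statistical structure the analysis
assumes, not the breeding program itself. A MAGIC funnel (half-diallele
crosses, generations of intermating, then single-seed descent) is *not*
re-enacted cross-by-cross: what the downstream methods see is only the
resulting genotype structure, so RILs are modelled directly as
founder-haplotype mosaics — per chromosome, a Poisson number of crossover
breakpoints splits the line into segments copied from random founders, the
line is homozygous for its mosaic, and a small per-locus probability
reintroduces residual heterozygosity.

Defaults (one choice, stated once):

| parameter | default | rationale |
|---|---|---|
| `n_founders` | 11 | founder count of the emulated population |
| `n_rils` | 550 | population size of the emulated RIL panel |
| `loci_per_chromosome` × `n_chromosomes` | 500 × 2 | a 1,000-variant VCF: large enough for stable filter-count checks, small enough to run everywhere |
| `recomb_rate` | 10 crossovers/chromosome | accumulated over the several effective meioses of a MAGIC funnel (order 1–2 per meiosis) |
| `residual_het_rate` | 0.01 | near-complete homozygosity after ~6 generations of selfing (2^-6 ≈ 0.016) |
| `n_genes`, `frac_eqtl` | 2000, 0.10 | a screen-sized gene compartment with a tenth eQTL-driven |
| `eqtl_fold` | 6 | a strong biallelic eQTL, the regime the bimodality filter targets |
| `noise_cv` | 0.2 | typical biological CV for moderately expressed genes; keeps unimodal pcSD near 33, well under the 45 threshold |
| baseline RPKM | lognormal(log 20, 1) | right-skewed, mostly tissue-expressed genes |
| `pheno_mu`, `beta_a`, `beta_d`, `beta_interact`, `pheno_sigma` | 30, 2, 1, 0, 1 | STR-like trait scale; two additive loci; `beta_interact = 0` encodes the additive-epistasis generative hypothesis (nonzero values support power studies) |
| `driver_founder_alt` | 3 of 11 | intermediate ALT frequency (~0.27) so all four genotype classes are populated |
| `n_family` | 278 | size of the emulated homology-derived family list |

Two **driver loci** (mid-chromosome 1 and 2) carry the phenotype effects;
the gene nearest each is forced to be eQTL-driven by it, and these two
driver genes are the ground-truth candidates the full pipeline should
recover. Driver-locus variants are written as high-QUAL MODERATE missense
annotations — they emulate *known, validated* candidate SNPs (the kind of
nonsynonymous variant such a study builds its phenotype model on), whereas
all other variants draw QUAL uniformly on (0, 1000) and impact from a
configurable distribution, since effect prediction itself is out of scope.
The family list is a random gene subset that always contains the two
driver genes, emulating candidates with literature precedent. The
ground-truth manifest (returned in memory and written as a flat key-value
file) lists every eQTL gene exactly once, the driver loci/genes and the
per-variant composition, so tests can predict filter-chain outputs
exactly.

Determinism: one config plus one seed yields byte-identical output files;
this is asserted in the tests.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium decay calibrated to a
real genetic map; allele-frequency spectra shaped by selection or
assortative mating; read-level noise (counts are skipped entirely —
expression is drawn directly on the RPKM scale); multi-allelic and indel
variants; shared-environment correlation between genes; real cotton
coordinates or gene density. With `frac_eqtl = 0.10` and near-perfect
recall, about 10% of synthetic genes pass the 45% gate, whereas an
empirical fiber transcriptome shows roughly 5% — the synthetic pass rate
tracks `frac_eqtl` by construction and is not evidence about the
empirical fraction.

# Problem sizes and numerical checks

The test suite and the acceptance script regenerate everything from code:
filter-chain checks run on the default 1,000-record VCF; the bimodality
recall/false-positive check on 2,000 genes × 550 RILs at both timepoints
(recall of fold-6 eQTL genes ≥ 90%, non-eQTL false positives ≤ 5%); the
UPGMA oracle on 1,000 random matrices of up to 6 taxa; epistasis recovery
at n = 550 with a 1,000-replicate null calibration of the Type II A-term
test (rejection rate 5% ± binomial noise); and the end-to-end run checks
that the two driver genes carry the maximal evidence count. These sizes
were chosen as the smallest at which the binomial tolerances above are
meaningful.

# Known limitations

* The pcSD screen is a heuristic for bimodality, not a mixture test; a
  formal dip test or two-component fit is out of scope by design.
* UPGMA assumes a molecular clock (ultrametricity); for deeply structured
  germplasm a neighbor-joining or likelihood tree may be more faithful —
  the distance matrix is exported so users can feed it to `ape`.
* The epistasis module takes the phenotype vector as given; BLUP
  normalization across environments is deliberately upstream of this
  package.
* Evidence ranking weights all five flags equally; it is a presentation
  order, not a posterior probability.
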