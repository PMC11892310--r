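#' Configuration for the synthetic MAGIC population generator
#'
#' Bundles and validates every tunable of the simulator. Defaults emulate the
#' population the downstream mining assumes: 11 founder lines crossed into
#' ~550 near-homozygous recombinant inbred lines (RILs), a genome of two
#' chromosomes carrying 1,000 biallelic variants, 2,000 fiber-expressed genes
#' of which 10% carry an expression QTL (eQTL) with a 6-fold allelic effect,
#' and a quantitative trait (fiber strength, STR) controlled additively by two
#' designated driver loci.
#'
#' @param n_founders number of founder lines (default 11).
#' @param n_rils number of recombinant inbred lines (default 550).
#' @param n_chromosomes number of chromosomes (default 2; the two driver loci
#'   sit on the first two chromosomes, or both on chromosome 1 if only one).
#' @param loci_per_chromosome biallelic variant loci per chromosome.
#' @param chrom_length_bp chromosome length in bp used for coordinates.
#' @param recomb_rate expected number of crossovers per chromosome accumulated
#'   over the whole breeding funnel (Poisson mean per RIL chromosome).
#' @param residual_het_rate probability that a RIL locus remains heterozygous
#'   after inbreeding; must lie in \[0, 0.05\].
#' @param n_genes number of genes in the expression compartment.
#' @param frac_eqtl fraction of genes whose expression is driven by an eQTL.
#' @param eqtl_fold multiplicative expression effect of the homozygous ALT
#'   genotype at the driving locus (heterozygotes get `sqrt(eqtl_fold)`).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   expression noise.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of per-gene
#'   baseline expression (RPKM units).
#' @param pheno_mu,beta_a,beta_d,beta_interact,pheno_sigma phenotype model:
#'   `mu + beta_a*I(A==ALT/ALT) + beta_d*I(D==ALT/ALT) +
#'   beta_interact*I(both) + N(0, pheno_sigma)` in trait units.
#' @param impact_probs named probabilities for drawing SnpEff-style impact
#'   labels (HIGH, MODERATE, LOW, MODIFIER) for non-driver variants.
#' @param driver_founder_alt number of founders carrying the ALT allele at the
#'   two designated driver loci (controls their RIL allele frequency).
#' @param n_family size of the emitted gene-family list (emulating a
#'   homology-derived candidate-family table).
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   datasets.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_magic()]
#' @export
sim_config <- function(n_founders = 11, n_rils = 550, n_chromosomes = 2,
                       loci_per_chromosome = 500, chrom_length_bp = 1e8,
                       recomb_rate = 10, residual_het_rate = 0.01,
                       n_genes = 2000, frac_eqtl = 0.10, eqtl_fold = 6,
                       noise_cv = 0.2, baseline_meanlog = log(20),
                       baseline_sdlog = 1,
                       pheno_mu = 30, beta_a = 2, beta_d = 1,
                       beta_interact = 0, pheno_sigma = 1,
                       impact_probs = c(HIGH = 0.05, MODERATE = 0.25,
                                        LOW = 0.30, MODIFIER = 0.40),
                       driver_founder_alt = 3, n_family = 278, seed = 1L) {
  assert_count(n_founders, "n_founders")
  assert_count(n_rils, "n_rils")
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(loci_per_chromosome, "loci_per_chromosome")
  assert_count(n_genes, "n_genes")
  assert_num(recomb_rate, "recomb_rate", min = 0)
  assert_prob(residual_het_rate, "residual_het_rate", max = 0.05)
  assert_prob(frac_eqtl, "frac_eqtl")
  assert_num(eqtl_fold, "eqtl_fold", min = 0)
  assert_num(noise_cv, "noise_cv", min = 0)
  assert_num(pheno_sigma, "pheno_sigma", min = 0)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_arg("'seed' must be a single integer")
  if (n_chromosomes == 1 && loci_per_chromosome < 2)
    stop_arg("need at least 2 loci to place two driver loci")
  lv <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (!all(lv %in% names(impact_probs)) || any(impact_probs < 0))
    stop_arg("'impact_probs' must name nonnegative HIGH/MODERATE/LOW/MODIFIER")
  impact_probs <- impact_probs[lv] / sum(impact_probs[lv])
  if (driver_founder_alt < 1 || driver_founder_alt > n_founders)
    stop_arg("'driver_founder_alt' must be in [1, n_founders]")
  structure(list(
    n_founders = as.integer(n_founders), n_rils = as.integer(n_rils),
    n_chromosomes = as.integer(n_chromosomes),
    loci_per_chromosome = as.integer(loci_per_chromosome),
    chrom_length_bp = chrom_length_bp, recomb_rate = recomb_rate,
    residual_het_rate = residual_het_rate, n_genes = as.integer(n_genes),
    frac_eqtl = frac_eqtl, eqtl_fold = eqtl_fold, noise_cv = noise_cv,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    pheno_mu = pheno_mu, beta_a = beta_a, beta_d = beta_d,
    beta_interact = beta_interact, pheno_sigma = pheno_sigma,
    impact_probs = impact_probs,
    driver_founder_alt = as.integer(driver_founder_alt),
    n_family = as.integer(n_family), seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MAGIC simulation config:",
      x$n_founders, "founders,", x$n_rils, "RILs,",
      x$n_chromosomes, "x", x$loci_per_chromosome, "loci,",
      x$n_genes, "genes (", round(100 * x$frac_eqtl), "% eQTL, fold",
      x$eqtl_fold, "), seed", x$seed, "\n")
  invisible(x)
}

chrom_names <- function(config) sprintf("chr%02d", seq_len(config$n_chromosomes))

#' Simulate founder haplotypes
#'
#' Draws a biallelic founder panel: for every locus an ALT allele is assigned
#' to a random nonempty subset of founders, so each locus is carried by at
#' least one founder and (with >= 2 founders) is polymorphic in the panel.
#' Two driver loci (near the middle of the first two chromosomes) are fixed to
#' carry ALT in exactly `driver_founder_alt` founders; they later drive the
#' two phenotype effects and the two designated eQTL driver genes.
#'
#' @param config a [sim_config()].
#' @return object of class `founder_panel`: list with `haplotypes`
#'   (founders x loci 0/1 matrix of ALT indicators), `loci` (data.frame with
#'   chrom, pos, ref, alt, locus id), and `drivers` (named character vector of
#'   the two driver locus ids, A and D).
#' @export
simulate_founders <- function(config) {
  if (!inherits(config, "sim_config")) stop_arg("config must be a sim_config")
  set.seed(config$seed)
  chroms <- chrom_names(config)
  L <- config$loci_per_chromosome
  loci <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, L))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  bases <- c("A", "C", "G", "T")
  loci$ref <- sample(bases, nrow(loci), replace = TRUE)
  loci$alt <- vapply(loci$ref, function(r) sample(setdiff(bases, r), 1), "")
  loci$locus <- paste0(loci$chrom, ":", loci$pos)
  rownames(loci) <- NULL

  nf <- config$n_founders
  # ALT founder count per locus: uniform on 1..max(1, nf-1) keeps loci
  # polymorphic in the panel whenever nf >= 2
  kmax <- max(1L, nf - 1L)
  k <- sample.int(kmax, nrow(loci), replace = TRUE)
  hap <- matrix(0L, nrow = nf, ncol = nrow(loci),
                dimnames = list(sprintf("founder%02d", seq_len(nf)), loci$locus))
  for (j in seq_len(nrow(loci))) hap[sample.int(nf, k[j]), j] <- 1L

  # designated driver loci: middle of chr 1 and chr 2 (or 1/3 and 2/3 of a
  # single chromosome)
  if (config$n_chromosomes >= 2) {
    ia <- which(loci$chrom == chroms[1]); ia <- ia[ceiling(length(ia) / 2)]
    id <- which(loci$chrom == chroms[2]); id <- id[ceiling(length(id) / 2)]
  } else {
    ia <- ceiling(nrow(loci) / 3); id <- ceiling(2 * nrow(loci) / 3)
  }
  for (j in c(ia, id)) {
    hap[, j] <- 0L
    hap[sample.int(nf, config$driver_founder_alt), j] <- 1L
  }
  drivers <- c(A = loci$locus[ia], D = loci$locus[id])

  structure(list(haplotypes = hap, loci = loci, drivers = drivers,
                 config = config), class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder panel:", nrow(x$haplotypes), "founders x", ncol(x$haplotypes),
      "loci; drivers", paste(x$drivers, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate recombinant inbred lines as founder-haplotype mosaics
#'
#' Each RIL chromosome is a mosaic of founder haplotypes: a Poisson number of
#' crossovers (mean `recomb_rate`) splits the chromosome into segments, each
#' copied from a random founder. The line is taken homozygous for its mosaic
#' haplotype, then a small fraction of loci (`residual_het_rate`) is reset to
#' heterozygous to emulate residual heterozygosity after single-seed descent.
#'
#' @param panel a [simulate_founders()] result.
#' @param config the same [sim_config()].
#' @return integer matrix RILs x loci of ALT dosages (0 = hom-REF, 1 = het,
#'   2 = hom-ALT), with RIL ids as rownames and locus ids as colnames.
#' @export
simulate_rils <- function(panel, config = panel$config) {
  if (!inherits(panel, "founder_panel")) stop_arg("panel must be a founder_panel")
  loci <- panel$loci
  nf <- config$n_founders
  geno <- matrix(0L, nrow = config$n_rils, ncol = nrow(loci),
                 dimnames = list(sprintf("RIL%04d", seq_len(config$n_rils)),
                                 loci$locus))
  chrom_idx <- split(seq_len(nrow(loci)), loci$chrom)
  for (i in seq_len(config$n_rils)) {
    hap <- integer(nrow(loci))
    for (idx in chrom_idx) {
      pos <- loci$pos[idx]
      nx <- stats::rpois(1, config$recomb_rate)
      brk <- sort(stats::runif(nx, min = 0, max = config$chrom_length_bp))
      seg <- findInterval(pos, brk) + 1L            # segment index per locus
      founder_of_seg <- sample.int(nf, nx + 1L, replace = TRUE)
      hap[idx] <- panel$haplotypes[cbind(founder_of_seg[seg], idx)]
    }
    geno[i, ] <- 2L * hap
  }
  if (config$residual_het_rate > 0) {
    flip <- matrix(stats::runif(length(geno)) < config$residual_het_rate,
                   nrow = nrow(geno))
    geno[flip] <- 1L
  }
  geno
}

#' Lay out genes and assign eQTLs
#'
#' Places `n_genes` genes evenly across the chromosomes, draws lognormal
#' baseline expression and gene lengths, and assigns an eQTL driver locus (on
#' the gene's own chromosome) to a `frac_eqtl` fraction of genes. The gene
#' nearest each phenotype driver locus is forced to be eQTL-driven by that
#' locus: these two "driver genes" are the ground-truth candidates the full
#' pipeline should recover.
#'
#' @param panel a [simulate_founders()] result.
#' @param config the same [sim_config()].
#' @return list of class `gene_layout`: `coords` (gene_id, chrom, start, end,
#'   length_bp), `baseline` (RPKM), `eqtl` (data.frame gene_id, locus, fold),
#'   `driver_genes` (named A/D character vector).
#' @export
simulate_genes <- function(panel, config = panel$config) {
  loci <- panel$loci
  chroms <- chrom_names(config)
  per <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
  coords <- do.call(rbind, Map(function(ch, n) {
    start <- sort(sample.int(config$chrom_length_bp - 3e4, n))
    len <- pmin(3e4, pmax(200, round(stats::rlnorm(n, log(2500), 0.6))))
    data.frame(chrom = ch, start = start, end = start + len - 1,
               length_bp = len, stringsAsFactors = FALSE)
  }, chroms, per))
  coords <- data.frame(gene_id = sprintf("gene%05d", seq_len(nrow(coords))),
                       coords, stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  baseline <- stats::rlnorm(nrow(coords), config$baseline_meanlog,
                            config$baseline_sdlog)
  names(baseline) <- coords$gene_id

  mid <- (coords$start + coords$end) / 2
  nearest_gene <- function(locus) {
    p <- loci[match(locus, loci$locus), ]
    cand <- which(coords$chrom == p$chrom)
    cand[which.min(abs(mid[cand] - p$pos))]
  }
  gi_a <- nearest_gene(panel$drivers["A"])
  gi_d <- nearest_gene(panel$drivers["D"])
  driver_genes <- c(A = coords$gene_id[gi_a], D = coords$gene_id[gi_d])

  n_eqtl <- round(config$frac_eqtl * config$n_genes)
  eqtl_idx <- unique(c(gi_a, gi_d,
                       sample(setdiff(seq_len(nrow(coords)), c(gi_a, gi_d)),
                              max(0, n_eqtl - 2))))
  eqtl <- data.frame(gene_id = coords$gene_id[eqtl_idx],
                     locus = NA_character_, fold = config$eqtl_fold,
                     stringsAsFactors = FALSE)
  for (r in seq_len(nrow(eqtl))) {
    gi <- eqtl_idx[r]
    if (gi == gi_a) { eqtl$locus[r] <- panel$drivers["A"]; next }
    if (gi == gi_d) { eqtl$locus[r] <- panel$drivers["D"]; next }
    same <- which(loci$chrom == coords$chrom[gi])
    eqtl$locus[r] <- loci$locus[sample(same, 1)]
  }
  structure(list(coords = coords, baseline = baseline, eqtl = eqtl,
                 driver_genes = driver_genes), class = "gene_layout")
}

#' Simulate a population expression matrix for one timepoint
#'
#' Non-eQTL genes: `baseline * noise`. eQTL genes:
#' `baseline * fold^(dosage/2) * noise`, where dosage is the RIL's ALT dosage
#' at the driving locus. Noise is multiplicative lognormal with unit mean and
#' coefficient of variation `noise_cv` (exactly 1 when `noise_cv = 0`).
#'
#' @param genotypes RILs x loci dosage matrix from [simulate_rils()].
#' @param genes a [simulate_genes()] layout.
#' @param config the [sim_config()].
#' @return genes x samples numeric matrix of RPKM values.
#' @export
simulate_expression <- function(genotypes, genes, config) {
  mu <- matrix(genes$baseline, nrow = nrow(genes$coords),
               ncol = nrow(genotypes),
               dimnames = list(genes$coords$gene_id, rownames(genotypes)))
  if (nrow(genes$eqtl) > 0 && config$eqtl_fold != 1) {
    dos <- t(genotypes[, genes$eqtl$locus, drop = FALSE])  # eqtl x rils
    mu[genes$eqtl$gene_id, ] <- mu[genes$eqtl$gene_id, , drop = FALSE] *
      genes$eqtl$fold^(dos / 2)
  }
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- matrix(stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog),
                    nrow = nrow(mu))
    mu <- mu * noise
  }
  mu
}

#' Simulate the two-locus additive phenotype
#'
#' `value = pheno_mu + beta_a*I(A == hom-ALT) + beta_d*I(D == hom-ALT) +
#' beta_interact*I(both) + Normal(0, pheno_sigma)`.
#'
#' @param genotypes RILs x loci dosage matrix.
#' @param config a [sim_config()].
#' @param drivers named character vector with elements `A` and `D` giving the
#'   driver locus ids (columns of `genotypes`).
#' @param trait trait name used in the output.
#' @return data.frame with columns ril_id, trait, value.
#' @export
simulate_phenotype <- function(genotypes, config, drivers, trait = "STR") {
  if (is.null(drivers) || !all(c("A", "D") %in% names(drivers)) ||
      !all(drivers[c("A", "D")] %in% colnames(genotypes)))
    stop_arg("driver loci A and D must name columns of the genotype matrix")
  a <- genotypes[, drivers["A"]] == 2L
  d <- genotypes[, drivers["D"]] == 2L
  value <- config$pheno_mu + config$beta_a * a + config$beta_d * d +
    config$beta_interact * (a & d) +
    stats::rnorm(nrow(genotypes), 0, config$pheno_sigma)
  data.frame(ril_id = rownames(genotypes), trait = trait, value = value,
             stringsAsFactors = FALSE, row.names = NULL)
}

# index of the nearest value of `centers` (sorted ascending) for each x
nearest_sorted <- function(x, centers) {
  j <- findInterval(x, centers)
  lo <- pmax(1L, j)
  hi <- pmin(length(centers), j + 1L)
  ifelse(abs(x - centers[lo]) <= abs(centers[hi] - x), lo, hi)
}

annotate_variants <- function(panel, genes, genotypes, config) {
  loci <- panel$loci
  mid <- (genes$coords$start + genes$coords$end) / 2
  gene_of <- character(nrow(loci))
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    gi <- which(genes$coords$chrom == ch)
    ord <- gi[order(mid[gi])]
    gene_of[li] <- genes$coords$gene_id[ord[nearest_sorted(loci$pos[li], mid[ord])]]
  }
  impact <- sample(names(config$impact_probs), nrow(loci), replace = TRUE,
                   prob = config$impact_probs)
  # the candidate loci the phenotype model is built on emulate known
  # high-confidence nonsynonymous SNPs: MODERATE missense, high QUAL
  di <- match(panel$drivers, loci$locus)
  impact[di] <- "MODERATE"
  qual <- round(stats::runif(nrow(loci), 0, 1000), 1)
  qual[di] <- round(stats::runif(2, 800, 1000), 1)
  n_hom_alt <- colSums(genotypes == 2L)
  n_het <- colSums(genotypes == 1L)
  data.frame(loci, qual = qual, impact = impact, gene_id = gene_of,
             n_hom_alt = n_hom_alt, n_het = n_het,
             n_hom_ref = colSums(genotypes == 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete synthetic MAGIC dataset
#'
#' Runs the whole generator under one seed: founder panel, RIL genotype
#' mosaics, gene layout with eQTL assignment, expression matrices for the two
#' developmental timepoints (8- and 16-DPA), the two-locus phenotype, variant
#' annotations (QUAL, SnpEff-style impact, nearest-gene id), a gene-family
#' list and QTL intervals (driver locus +/- 2 Mb). The returned object is the
#' ground-truth manifest for every downstream check.
#'
#' @param config a [sim_config()].
#' @return object of class `magic_sim` with elements `config`, `panel`,
#'   `genotypes`, `genes`, `expr` (list `dpa8`, `dpa16`), `phenotype`,
#'   `variants`, `family`, `qtl`.
#' @examples
#' sim <- simulate_magic(sim_config(n_rils = 40, loci_per_chromosome = 30,
#'                                  n_genes = 100, seed = 7))
#' sim
#' @export
simulate_magic <- function(config = sim_config()) {
  panel <- simulate_founders(config)        # seeds the RNG with config$seed
  genotypes <- simulate_rils(panel, config)
  genes <- simulate_genes(panel, config)
  expr <- list(dpa8 = simulate_expression(genotypes, genes, config),
               dpa16 = simulate_expression(genotypes, genes, config))
  phenotype <- simulate_phenotype(genotypes, config, panel$drivers)
  variants <- annotate_variants(panel, genes, genotypes, config)
  family <- sort(unique(c(genes$driver_genes,
                          sample(genes$coords$gene_id,
                                 min(config$n_family, config$n_genes)))))
  pos <- panel$loci$pos[match(panel$drivers, panel$loci$locus)]
  ch <- panel$loci$chrom[match(panel$drivers, panel$loci$locus)]
  qtl <- data.frame(name = c("qA-STR", "qD-STR"), trait = "STR", chrom = ch,
                    start = pmax(1, pos - 2e6), end = pos + 2e6,
                    stringsAsFactors = FALSE)
  structure(list(config = config, panel = panel, genotypes = genotypes,
                 genes = genes, expr = expr, phenotype = phenotype,
                 variants = variants, family = family, qtl = qtl),
            class = "magic_sim")
}

#' @export
print.magic_sim <- function(x, ...) {
  cat("Synthetic MAGIC dataset:\n")
  cat(" ", nrow(x$genotypes), "RILs x", ncol(x$genotypes), "loci (",
      x$config$n_founders, "founders )\n")
  cat(" ", nrow(x$genes$coords), "genes,", nrow(x$genes$eqtl),
      "with an eQTL; driver genes",
      paste(x$genes$driver_genes, collapse = ", "), "\n")
  cat("  driver loci", paste(x$panel$drivers, collapse = ", "), "\n")
  invisible(x)
}

format_gt <- function(dosage) c("0/0", "0/1", "1/1")[dosage + 1L]

write_sim_vcf <- function(sim, path) {
  v <- sim$variants
  effect <- c(HIGH = "stop_gained", MODERATE = "missense_variant",
              LOW = "synonymous_variant", MODIFIER = "intergenic_region")
  ann <- sprintf("ANN=%s|%s|%s|%s|%s|transcript", v$alt, effect[v$impact],
                 v$impact, v$gene_id, v$gene_id)
  gt <- apply(sim$genotypes, 1, format_gt)       # loci x rils
  header <- c("##fileformat=VCFv4.2",
              "##source=multimine-simulator",
              sprintf("##contig=<ID=%s,length=%d>", chrom_names(sim$config),
                      as.integer(sim$config$chrom_length_bp)),
              paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=",
                     "\"Functional annotations: 'Allele|Annotation|",
                     "Annotation_Impact|Gene_Name|Gene_ID|Feature_Type'\">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(sim$genotypes)),
                    collapse = "\t"))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, sprintf("%.1f", v$qual),
                "PASS", ann, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits the file set the mining pipeline consumes: a SnpEff-style annotated
#' VCF v4.2 (`variants.vcf`), expression TSVs per timepoint (`expr_8dpa.tsv`,
#' `expr_16dpa.tsv`; genes in rows, RILs in columns), gene lengths
#' (`gene_lengths.tsv`), gene coordinates (`gene_coords.tsv`, 1-based
#' inclusive), a phenotype CSV (`phenotype.csv`), the gene-family list
#' (`family.tsv`), QTL intervals (`qtl.tsv`, 1-based inclusive) and a flat
#' key-value ground-truth manifest (`manifest.tsv`) listing, among other
#' things, every simulated eQTL gene exactly once.
#'
#' @param sim a [simulate_magic()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_dataset <- function(sim, dir) {
  if (!inherits(sim, "magic_sim")) stop_arg("sim must be a magic_sim")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to directory: ", dir)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             expr8 = file.path(dir, "expr_8dpa.tsv"),
             expr16 = file.path(dir, "expr_16dpa.tsv"),
             lengths = file.path(dir, "gene_lengths.tsv"),
             coords = file.path(dir, "gene_coords.tsv"),
             pheno = file.path(dir, "phenotype.csv"),
             family = file.path(dir, "family.tsv"),
             qtl = file.path(dir, "qtl.tsv"),
             manifest = file.path(dir, "manifest.tsv"))
  write_sim_vcf(sim, paths["vcf"])
  write_matrix_tsv(round(sim$expr$dpa8, 4), paths["expr8"])
  write_matrix_tsv(round(sim$expr$dpa16, 4), paths["expr16"])
  utils::write.table(
    data.frame(gene_id = sim$genes$coords$gene_id,
               length_bp = sim$genes$coords$length_bp),
    paths["lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    sim$genes$coords[, c("gene_id", "chrom", "start", "end")],
    paths["coords"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$phenotype, paths["pheno"], quote = FALSE,
                   row.names = FALSE)
  utils::write.table(data.frame(gene_id = sim$family), paths["family"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$qtl, paths["qtl"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kv <- rbind(
    data.frame(key = c("n_founders", "n_rils", "n_loci", "n_genes", "seed",
                       "driver_locus_A", "driver_locus_D",
                       "driver_gene_A", "driver_gene_D"),
               value = c(sim$config$n_founders, sim$config$n_rils,
                         ncol(sim$genotypes), nrow(sim$genes$coords),
                         sim$config$seed, sim$panel$drivers[["A"]],
                         sim$panel$drivers[["D"]],
                         sim$genes$driver_genes[["A"]],
                         sim$genes$driver_genes[["D"]])),
    data.frame(key = paste0("eqtl.", sim$genes$eqtl$gene_id),
               value = paste0(sim$genes$eqtl$locus, ":fold=",
                              sim$genes$eqtl$fold)))
  utils::write.table(kv, paths["manifest"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
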