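test_that("IBS distance implements the allele-sharing table", {
  g <- rbind(a = c(0, 0, 0), b = c(2, 2, 2), c = c(1, 0, 2))
  d <- ibs_distance(g)
  expect_equal(d$d["a", "b"], 1)                    # opposite homozygotes
  expect_equal(d$d["a", "a"], 0)
  # a vs c: het 0.5, identical 1, opposite 0 -> mean 0.5 -> distance 0.5
  expect_equal(d$d["a", "c"], 0.5)
  # single locus, hom-ref vs het
  d1 <- ibs_distance(rbind(x = 0, y = 1))
  expect_equal(d1$d["x", "y"], 0.5)
  # het vs het: 1 by default, 0.5 under the strict convention
  dh <- ibs_distance(rbind(x = 1, y = 1))
  expect_equal(dh$d["x", "y"], 0)
  dh2 <- ibs_distance(rbind(x = 1, y = 1), het_het = 0.5)
  expect_equal(dh2$d["x", "y"], 0.5)
  # missing loci are skipped per pair; all-missing pair errors
  gm <- rbind(a = c(0, NA, 2), b = c(0, 2, NA))
  dm <- ibs_distance(gm)
  expect_equal(dm$d["a", "b"], 0)
  expect_equal(dm$n["a", "b"], 1)
  expect_error(ibs_distance(rbind(a = c(NA, 1), b = c(1, NA))),
               "comparable loci")
  expect_error(ibs_distance(g[1, , drop = FALSE]), "2 taxa")
})

test_that("UPGMA reproduces hand-worked examples", {
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 4)
  expect_identical(to_newick(t2), "(A:2,B:2);")
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_identical(to_newick(upgma(d3)), "((A:1,B:1):2,C:3);")
  expect_error(upgma(d3[1, 1, drop = FALSE]), "2 taxa")
})

test_that("UPGMA agrees with average-linkage hclust on random matrices", {
  set.seed(101)
  for (r in 1:300) {
    n <- sample(3:6, 1)
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- round(runif(n * (n - 1) / 2), 3)
    m <- m + t(m)
    labs <- paste0("t", seq_len(n))
    dimnames(m) <- list(labs, labs)
    mine <- as.matrix(cophenetic(upgma(m)))[labs, labs]
    ref <- as.matrix(cophenetic(hclust(as.dist(m), method = "average")))
    expect_lt(max(abs(mine - ref[labs, labs])), 1e-10)
  }
})

test_that("UPGMA matches phangorn::upgma edge lengths", {
  set.seed(5)
  m <- as.matrix(dist(matrix(rnorm(60), 6)))
  labs <- paste0("s", 1:6)
  dimnames(m) <- list(labs, labs)
  mine <- ape::read.tree(text = to_newick(upgma(m)))
  ref <- phangorn::upgma(as.dist(m))
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(mine))[labs, labs]),
               unname(as.matrix(ape::cophenetic.phylo(ref))[labs, labs]),
               tolerance = 1e-6)
})

test_that("trees are ultrametric and cophenetically faithful", {
  # build an ultrametric input from a random tree, then recover it exactly
  set.seed(33)
  m <- as.matrix(dist(matrix(rnorm(50), 5)))
  labs <- paste0("u", 1:5)
  dimnames(m) <- list(labs, labs)
  ultra <- as.matrix(cophenetic(upgma(m)))[labs, labs]  # ultrametric matrix
  rec <- as.matrix(cophenetic(upgma(ultra)))[labs, labs]
  expect_equal(rec, ultra, tolerance = 1e-12)
  # every leaf sits at height 0: root-path lengths all equal root height
  tr <- ape::read.tree(text = to_newick(upgma(m)))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
})

test_that("taxon order does not change topology or heights", {
  set.seed(77)
  m <- as.matrix(dist(matrix(rnorm(60), 6)))
  labs <- paste0("p", 1:6)
  dimnames(m) <- list(labs, labs)
  t1 <- upgma(m)
  perm <- sample(6)
  t2 <- upgma(m[perm, perm])
  c1 <- as.matrix(cophenetic(t1))[labs, labs]
  c2 <- as.matrix(cophenetic(t2))[labs, labs]
  expect_equal(c1, c2, tolerance = 1e-12)
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-12)
})

test_that("newick output round-trips through ape and quotes labels", {
  set.seed(8)
  m <- as.matrix(dist(matrix(rnorm(40), 4)))
  labs <- c("Line 1", "L(2)", "plain", "x:y")
  dimnames(m) <- list(labs, labs)
  tw <- to_newick(upgma(m))
  expect_match(tw, "'Line 1'", fixed = TRUE)
  expect_match(tw, ";$")
  tr <- ape::read.tree(text = tw)
  # ape keeps the quotes in tip labels; strip them before comparing
  unq <- function(x) gsub("''", "'", sub("^'(.*)'$", "\\1", x))
  expect_setequal(unq(tr$tip.label), labs)
  cp <- as.matrix(ape::cophenetic.phylo(tr))
  dimnames(cp) <- list(unq(rownames(cp)), unq(colnames(cp)))
  expect_equal(unname(cp[labs, labs]),
               unname(as.matrix(cophenetic(upgma(m)))[labs, labs]),
               tolerance = 1e-6)
})

test_that("outgroup handling follows UPGMA geometry", {
  g <- rbind(a = c(0, 0, 2, 0), b = c(0, 2, 2, 0), c = c(0, 0, 2, 2))
  # near-maximally distant outgroup merges last
  d <- with_outgroup(g, c(2, 2, 0, 2), label = "OG")
  tr <- upgma(d)
  last <- tr$merge[nrow(tr$merge), ]
  expect_true(-match("OG", tr$labels) %in% last)
  # outgroup identical to one taxon merges with it first
  d2 <- with_outgroup(g, g["b", ], label = "OG")
  t2 <- upgma(d2)
  first <- sort(t2$merge[1, ])
  expect_equal(first, sort(-match(c("b", "OG"), t2$labels)))
  expect_error(with_outgroup(g, c(0, 2)), "same")
})

test_that("a divergent reference lineage is basal in the region tree", {
  # tight ingroup (three nearly identical lines) vs an opposite-homozygote
  # outgroup: the outgroup must be the last-merged lineage
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("chr01", "100", ".", "A", "G", "900", "PASS", ".", "GT",
            "0/0", "0/0", "0/0"), collapse = "\t"),
    paste(c("chr01", "200", ".", "C", "T", "900", "PASS", ".", "GT",
            "0/0", "0/0", "0/1"), collapse = "\t")), path)
  vs <- read_snpeff_vcf(path)
  rt <- region_tree(vs, "chr01", 1, 1e9, min_qual = 0,
                    outgroup = c(2L, 2L), outgroup_label = "GB379")
  expect_equal(rt$n_loci, 2)
  last <- rt$tree$merge[nrow(rt$tree$merge), ]
  expect_true(-match("GB379", rt$tree$labels) %in% last)
})

test_that("gene-overlap restriction keeps a subset of the region's loci", {
  # gene-dense toy genome so the gene-overlap restriction keeps some loci
  cfg <- small_config(seed = 61, chrom_length_bp = 4e5)
  sim <- simulate_magic(cfg)
  dir <- tempfile()
  vs <- read_snpeff_vcf(write_dataset(sim, dir)["vcf"])
  rt_all <- region_tree(vs, "chr01", 1, 1e9)
  rt_gene <- region_tree(vs, "chr01", 1, 1e9, coords = sim$genes$coords)
  expect_lt(rt_gene$n_loci, rt_all$n_loci)
  expect_gt(rt_gene$n_loci, 0)
  expect_equal(nrow(rt_gene$dist$d), length(vs$samples))
})
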