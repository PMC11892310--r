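#' Identity-by-state distance matrix
#'
#' Pairwise genotype distance between taxa over a set of biallelic loci. Per
#' locus the allele-sharing similarity of two diploid dosage calls is
#' `1 - |d1 - d2| / 2`: identical homozygotes 1, het vs any homozygote 0.5,
#' opposite homozygotes 0, and het vs het 1 under the default unordered-pair
#' convention (`het_het = 1`; set `het_het = 0.5` for the strict convention
#' that a heterozygote shares only one allele in expectation). Loci where
#' either call is missing are skipped for that pair. The distance is
#' `1 - mean(similarity)` over the compared loci.
#'
#' @param genotypes taxa x loci matrix of ALT dosages (0/1/2, NA = missing),
#'   taxa ids as rownames.
#' @param het_het similarity assigned to het-vs-het pairs (1 or 0.5).
#' @return object of class `ibs_dist`: list with `d` (symmetric taxa x taxa
#'   distance matrix in \[0, 1\]) and `n` (loci compared per pair).
#' @export
ibs_distance <- function(genotypes, het_het = 1) {
  genotypes <- as.matrix(genotypes)
  nt <- nrow(genotypes)
  if (nt < 2) stop_arg("need >= 2 taxa")
  if (ncol(genotypes) < 1) stop_arg("need >= 1 locus")
  taxa <- rownames(genotypes) %||% paste0("taxon", seq_len(nt))
  # dissimilarity per locus is |d1 - d2| / 2 (plus an optional het-het
  # penalty); accumulate it over all pairs at once with indicator-matrix
  # products so the cost is a few BLAS calls, not an R-level pair loop
  A <- (genotypes == 0) + 0; A[is.na(A)] <- 0      # hom-REF
  H <- (genotypes == 1) + 0; H[is.na(H)] <- 0      # het
  B <- (genotypes == 2) + 0; B[is.na(B)] <- 0      # hom-ALT
  AB <- A %*% t(B)
  AH <- (A + B) %*% t(H)
  diff_sum <- 2 * (AB + t(AB)) + AH + t(AH)        # sum over loci of |d1-d2|
  if (het_het != 1) diff_sum <- diff_sum + 2 * (1 - het_het) * (H %*% t(H))
  V <- (!is.na(genotypes)) + 0
  n <- V %*% t(V)                                  # comparable loci per pair
  if (any(n[upper.tri(n)] == 0)) {
    bad <- which(n == 0 & upper.tri(n), arr.ind = TRUE)[1, ]
    stop_arg("taxa '", taxa[bad[1]], "' and '", taxa[bad[2]],
             "' share no comparable loci")
  }
  d <- diff_sum / (2 * n)
  diag(d) <- 0
  dimnames(d) <- dimnames(n) <- list(taxa, taxa)
  structure(list(d = d, n = n), class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat("IBS distance matrix over", nrow(x$d), "taxa\n")
  print(round(x$d, 4))
  invisible(x)
}

#' Append an outgroup taxon before distance computation
#'
#' Adds an outgroup genotype vector (over the same loci) as an extra taxon and
#' recomputes the IBS distance matrix. UPGMA trees are inherently rooted; the
#' outgroup's attachment point orients that root against a reference lineage.
#'
#' @param genotypes ingroup taxa x loci dosage matrix.
#' @param outgroup dosage vector over the same loci (same length/order as the
#'   columns of `genotypes`).
#' @param label taxon label for the outgroup.
#' @param het_het passed to [ibs_distance()].
#' @return an `ibs_dist` including the outgroup.
#' @export
with_outgroup <- function(genotypes, outgroup, label = "outgroup",
                          het_het = 1) {
  genotypes <- as.matrix(genotypes)
  if (length(outgroup) != ncol(genotypes))
    stop_arg("outgroup must cover the same ", ncol(genotypes), " loci")
  m <- rbind(genotypes, matrix(outgroup, nrow = 1,
                               dimnames = list(label, colnames(genotypes))))
  ibs_distance(m, het_het = het_het)
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair-group agglomeration: repeatedly merge the two
#' closest clusters; the distance from the merged cluster to any other is the
#' size-weighted mean of its parts' distances (i.e. the unweighted mean over
#' leaves). Node height is half the merge distance, so leaves sit at height 0
#' and the tree is ultrametric. Distance ties are broken deterministically by
#' the lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its smallest leaf label).
#'
#' @param d an [ibs_distance()] result, a `dist`, or a symmetric matrix with
#'   labelled rows.
#' @return object of class `c("upgma_tree", "hclust")` with the usual
#'   `merge`, `height` (merge distances), `order` and `labels` elements, so
#'   [stats::cophenetic()], `plot()` and [ape::as.phylo()] all apply.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(d))   # ((A:1,B:1):2,C:3);
#' @export
upgma <- function(d) {
  if (inherits(d, "ibs_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  nt <- nrow(d)
  if (nt < 2) stop_arg("need >= 2 taxa")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop_arg("distance matrix must be symmetric with zero diagonal")
  labels <- rownames(d) %||% paste0("taxon", seq_len(nt))

  active <- as.list(seq_len(nt))          # leaf index sets per cluster
  node_of <- as.list(-seq_len(nt))        # hclust merge codes
  minlab <- labels                        # smallest leaf label per cluster
  size <- rep(1, nt)
  D <- d
  merge <- matrix(0L, nt - 1, 2)
  height <- numeric(nt - 1)

  for (step in seq_len(nt - 1)) {
    k <- length(active)
    # closest pair; among exact ties, the lexicographically smallest pair of
    # cluster labels wins
    Dm <- D
    Dm[lower.tri(Dm, diag = TRUE)] <- Inf
    dmin <- min(Dm)
    cand <- which(Dm == dmin, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      key <- apply(cand, 1, function(ij) {
        lab <- sort(minlab[ij])
        paste(lab[1], lab[2], sep = "\r")
      })
      cand <- cand[order(key)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    height[step] <- dmin
    # left child = cluster whose smallest leaf label sorts first, so the
    # serialized tree has a canonical child order
    if (minlab[j] < minlab[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(node_of[[i]], node_of[[j]])
    # weighted update = unweighted average over member leaves
    newrow <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    node_of <- c(node_of[keep], list(step))
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
    size <- c(size[keep], size[i] + size[j])
  }

  tr <- structure(list(merge = merge, height = height,
                       order = integer(0), labels = labels,
                       method = "average", call = match.call(),
                       dist.method = "ibs"),
                  class = c("upgma_tree", "hclust"))
  tr$order <- leaf_order(merge, nt)
  tr
}

leaf_order <- function(merge, nt) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over", length(x$labels), "taxa; root height",
      format(max(x$height) / 2), "\n")
  invisible(x)
}

#' UPGMA tree of samples over a genomic interval
#'
#' Convenience pipeline for the region-diversity view: restrict a variant set
#' to an interval, apply the quality gate, optionally keep only variants
#' falling inside annotated gene bodies, optionally add an outgroup genotype
#' vector, then compute the IBS distance matrix and the UPGMA tree.
#'
#' @param vs a `variant_set` from [read_snpeff_vcf()].
#' @param chrom,start,end interval (1-based inclusive).
#' @param min_qual QUAL gate applied before distance computation.
#' @param coords optional gene coordinate data.frame (gene_id, chrom, start,
#'   end); when supplied, only variants overlapping a gene are used.
#' @param outgroup optional dosage vector over the retained loci.
#' @param outgroup_label taxon label for the outgroup.
#' @param het_het passed to [ibs_distance()].
#' @return list with `tree` (a [upgma()] result), `dist` (the `ibs_dist`) and
#'   `n_loci` used.
#' @export
region_tree <- function(vs, chrom, start, end, min_qual = 500, coords = NULL,
                        outgroup = NULL, outgroup_label = "outgroup",
                        het_het = 1) {
  vs <- filter_quality(subset_interval(vs, chrom, start, end), min_qual)
  if (!is.null(coords)) {
    keep <- vapply(vs$variants$pos, function(p) {
      any(coords$chrom == chrom & coords$start <= p & coords$end >= p)
    }, logical(1))
    vs <- subset_records(vs, keep)
  }
  if (nrow(vs$variants) == 0) stop_arg("no variants left in the interval")
  gt <- t(vs$gt)
  colnames(gt) <- paste0(vs$variants$chrom, ":", vs$variants$pos)
  d <- if (is.null(outgroup)) ibs_distance(gt, het_het = het_het)
       else with_outgroup(gt, outgroup, label = outgroup_label,
                          het_het = het_het)
  list(tree = upgma(d), dist = d, n_loci = ncol(gt))
}

quote_newick_label <- function(lab) {
  needs <- grepl("[](),:;'[[:space:]]", lab)
  lab[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
  lab
}

#' Serialize a UPGMA tree to Newick
#'
#' Branch lengths are in distance units: a node created at merge distance h
#' sits at height h/2 and each branch length is the parent-child height
#' difference. Labels containing Newick metacharacters or whitespace are
#' single-quoted. The string is terminated by `;`.
#'
#' @param tree a [upgma()] result.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
to_newick <- function(tree, digits = 10) {
  if (!inherits(tree, "upgma_tree") && !inherits(tree, "hclust"))
    stop_arg("tree must be an upgma_tree/hclust")
  labs <- quote_newick_label(tree$labels)
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  rec <- function(node) {
    if (node < 0) return(list(str = labs[-node], h = 0))
    h <- tree$height[node] / 2
    l <- rec(tree$merge[node, 1])
    r <- rec(tree$merge[node, 2])
    list(str = paste0("(", l$str, ":", fmt(h - l$h), ",",
                      r$str, ":", fmt(h - r$h), ")"),
         h = h)
  }
  paste0(rec(nrow(tree$merge))$str, ";")
}
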