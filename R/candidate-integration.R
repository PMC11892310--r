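check_unique <- function(x, what) {
  if (anyDuplicated(x))
    stop_arg("duplicate gene ids in ", what, ": ",
             paste(unique(x[duplicated(x)]), collapse = ", "))
  x
}

#' Genes overlapping a genomic interval
#'
#' Any-overlap semantics on 1-based inclusive coordinates: a gene is returned
#' when `gene_start <= end + flank` and `gene_end >= start - flank`, so a gene
#' exactly abutting an interval bound is included.
#'
#' @param coords data.frame with columns gene_id, chrom, start, end.
#' @param chrom,start,end the interval (1-based inclusive).
#' @param flank widen the interval by this many bp on each side (default 0).
#' @return character vector of overlapping gene ids.
#' @export
genes_in_interval <- function(coords, chrom, start, end, flank = 0) {
  if (start > end) stop_arg("start must be <= end")
  hit <- coords$chrom == chrom & coords$start <= end + flank &
    coords$end >= start - flank
  coords$gene_id[hit]
}

#' Integrate the evidence streams into a ranked candidate table
#'
#' One row per gene appearing in any input, with evidence flags:
#' `has_dna_variant` (membership in the allele-mining gene set),
#' `fiber_expressed` (top-decile mean > `p90_min` RPKM at either timepoint),
#' `bimodal_8dpa` / `bimodal_16dpa` (passing the bimodality filter at each
#' timepoint), `in_family` (member of the supplied gene-family list) and
#' `qtl_hits` (comma-joined names of overlapping QTL intervals).
#' `evidence_count` sums the five discovery flags — DNA variant, bimodal at
#' 8-DPA, bimodal at 16-DPA, family precedent, QTL overlap — and genes are
#' ranked by descending evidence_count, then descending maximum pcsd across
#' timepoints, then gene id. (`fiber_expressed` is reported but not counted:
#' it is a component of the bimodality gate, not independent evidence.)
#'
#' @param dna_genes character vector of genes with consequential DNA variants
#'   (from [genes_affected()] after the filter chain).
#' @param dispersion_8,dispersion_16 [dispersion_table()]s for the two
#'   timepoints.
#' @param family_list optional character vector of family-member gene ids.
#' @param gene_coords optional coordinates data.frame (gene_id, chrom, start,
#'   end) — required when `qtl_intervals` is given.
#' @param qtl_intervals optional data.frame (name, chrom, start, end; 1-based
#'   inclusive).
#' @param pcsd_min,p90_min bimodality thresholds (defaults 45 and 3).
#' @param flank QTL interval widening in bp.
#' @return data.frame of class `candidate_table`, ranked.
#' @export
annotate_candidates <- function(dna_genes, dispersion_8, dispersion_16,
                                family_list = NULL, gene_coords = NULL,
                                qtl_intervals = NULL, pcsd_min = 45,
                                p90_min = 3, flank = 0) {
  check_unique(dna_genes, "dna_genes")
  check_unique(dispersion_8$gene_id, "dispersion_8")
  check_unique(dispersion_16$gene_id, "dispersion_16")
  if (!is.null(family_list)) check_unique(family_list, "family_list")
  if (!is.null(qtl_intervals) && is.null(gene_coords))
    stop_arg("gene_coords required to resolve QTL overlaps")

  d8 <- bimodal_filter(dispersion_8, pcsd_min, p90_min)
  d16 <- bimodal_filter(dispersion_16, pcsd_min, p90_min)
  genes <- sort(unique(c(dna_genes, d8$gene_id, d16$gene_id,
                         family_list)))
  i8 <- match(genes, d8$gene_id)
  i16 <- match(genes, d16$gene_id)
  pcsd_max <- pmax(ifelse(is.na(i8), -Inf, d8$pcsd[i8]),
                   ifelse(is.na(i16), -Inf, d16$pcsd[i16]))

  qtl_hits <- rep("", length(genes))
  if (!is.null(qtl_intervals)) {
    check_unique(gene_coords$gene_id, "gene_coords")
    for (r in seq_len(nrow(qtl_intervals))) {
      hit <- genes %in% genes_in_interval(gene_coords,
                                          qtl_intervals$chrom[r],
                                          qtl_intervals$start[r],
                                          qtl_intervals$end[r], flank)
      qtl_hits[hit] <- ifelse(nzchar(qtl_hits[hit]),
                              paste(qtl_hits[hit], qtl_intervals$name[r],
                                    sep = ","),
                              qtl_intervals$name[r])
    }
  }

  out <- data.frame(
    gene_id = genes,
    has_dna_variant = genes %in% dna_genes,
    fiber_expressed = (!is.na(i8) & d8$passes_expression[i8]) |
      (!is.na(i16) & d16$passes_expression[i16]),
    bimodal_8dpa = !is.na(i8) & d8$bimodal[i8],
    bimodal_16dpa = !is.na(i16) & d16$bimodal[i16],
    in_family = if (is.null(family_list)) FALSE else genes %in% family_list,
    qtl_hits = qtl_hits,
    max_pcsd = ifelse(is.finite(pcsd_max), pcsd_max, NA_real_),
    stringsAsFactors = FALSE)
  out$evidence_count <- out$has_dna_variant + out$bimodal_8dpa +
    out$bimodal_16dpa + out$in_family + nzchar(out$qtl_hits)
  ord <- order(-out$evidence_count,
               -ifelse(is.na(out$max_pcsd), -Inf, out$max_pcsd),
               out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' @export
print.candidate_table <- function(x, n = 10, ...) {
  cat("Candidate table:", nrow(x), "genes; top", min(n, nrow(x)), "rows:\n")
  print.data.frame(utils::head(x, n), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Flammability-family screen
#'
#' Among a homology-derived gene-family list, returns the genes whose
#' expression is bimodal at BOTH developmental timepoints — the screen for
#' family members with segregating expression variants.
#'
#' @param family_list character vector of family gene ids.
#' @param dispersion_8,dispersion_16 [dispersion_table()]s.
#' @param pcsd_min,p90_min bimodality thresholds.
#' @return sorted character vector of gene ids.
#' @export
flammability_screen <- function(family_list, dispersion_8, dispersion_16,
                                pcsd_min = 45, p90_min = 3) {
  if (!length(family_list)) return(character(0))
  b8 <- bimodal_genes(dispersion_8, pcsd_min, p90_min)
  b16 <- bimodal_genes(dispersion_16, pcsd_min, p90_min)
  sort(intersect(family_list, intersect(b8, b16)))
}
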