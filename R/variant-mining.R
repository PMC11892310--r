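#' Read a SnpEff-annotated VCF into a variant set
#'
#' Parses a VCF v4.x file (via vcfR) and extracts the fields the allele-mining
#' filters need: position, alleles, QUAL, the SnpEff `ANN` annotations
#' (pipe-separated subfields in the order
#' `Allele|Annotation|Annotation_Impact|Gene_Name|Gene_ID|...`; the impact is
#' the 3rd subfield and the gene id the 5th) and per-sample genotype calls.
#' Both `/` and `|` genotype separators are accepted. Records without an `ANN`
#' key are kept with an empty annotation list; malformed ANN entries (fewer
#' than five subfields or an unknown impact level) are skipped with a warning.
#'
#' Genotype coding follows the homozygous-ALT convention of variant mining on
#' multiallelic records: a call is hom-alt when both alleles are the same
#' non-reference index, het when the two indices differ, hom-ref when both are
#' 0, and missing when any allele is missing.
#'
#' @param path path to a VCF file.
#' @return object of class `variant_set`: list with `variants` (data.frame
#'   chrom, pos, ref, alt, qual), `ann` (list, one data.frame per record with
#'   columns allele, effect, impact, gene_name, gene_id), `gt` (records x
#'   samples integer dosage matrix: 0 hom-ref, 1 het, 2 hom-alt, NA missing)
#'   and `samples`.
#' @export
read_snpeff_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- tryCatch(readLines(path, n = 1), error = function(e) "")
  if (!grepl("^##fileformat=VCF", first))
    stop("not a VCF file (missing ##fileformat header): ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.numeric(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                         stringsAsFactors = FALSE, row.names = NULL)
  ann_raw <- vcfR::extract.info(v, element = "ANN")
  ann <- lapply(ann_raw, parse_ann_field)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) {
    gt <- matrix(NA_integer_, nrow = nrow(variants), ncol = 0)
    samples <- character(0)
  } else {
    samples <- colnames(gt_raw)
    gt <- matrix(gt_to_dosage(gt_raw), nrow = nrow(gt_raw),
                 dimnames = list(NULL, samples))
  }
  structure(list(variants = variants, ann = ann, gt = gt, samples = samples),
            class = "variant_set")
}

impact_levels <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

parse_ann_field <- function(x) {
  empty <- data.frame(allele = character(0), effect = character(0),
                      impact = character(0), gene_name = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
  if (is.na(x) || !nzchar(x)) return(empty)
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], "|", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) >= 5 && p[3] %in% impact_levels,
               logical(1))
  if (any(!ok))
    warning(sum(!ok), " malformed ANN entr(y/ies) skipped", call. = FALSE)
  parts <- parts[ok]
  if (!length(parts)) return(empty)
  data.frame(allele = vapply(parts, `[`, "", 1),
             effect = vapply(parts, `[`, "", 2),
             impact = vapply(parts, `[`, "", 3),
             gene_name = vapply(parts, `[`, "", 4),
             gene_id = vapply(parts, `[`, "", 5),
             stringsAsFactors = FALSE, row.names = NULL)
}

# "0/0" -> 0, "0/1" -> 1, "1/1" -> 2, "2/2" -> 2, "1/2" -> 1, "./." -> NA;
# accepts '|' phasing and haploid calls (treated as homozygous)
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  dos <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (!length(al) || any(al %in% c(".", ""))) return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al)) return(NA_integer_)
    if (length(al) == 1) al <- c(al, al)
    if (all(al == 0)) 0L else if (al[1] == al[2]) 2L else 1L
  }, integer(1))
  dos[match(as.vector(gt), u)]
}

subset_records <- function(vs, keep) {
  vs$variants <- vs$variants[keep, , drop = FALSE]
  rownames(vs$variants) <- NULL
  vs$ann <- vs$ann[keep]
  vs$gt <- vs$gt[keep, , drop = FALSE]
  vs
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "records,", length(x$samples),
      "samples\n")
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$variants)

#' Filter variants on call quality
#'
#' Keeps records whose QUAL is strictly greater than `min_qual` (the mining
#' chain's high-confidence gate). Records with missing QUAL are excluded and
#' reported with a warning.
#'
#' @param vs a `variant_set`.
#' @param min_qual phred-scaled quality threshold (default 500; strict `>`).
#' @return the filtered `variant_set`, record order preserved.
#' @export
filter_quality <- function(vs, min_qual = 500) {
  q <- vs$variants$qual
  if (anyNA(q))
    warning(sum(is.na(q)), " record(s) with missing QUAL excluded",
            call. = FALSE)
  subset_records(vs, !is.na(q) & q > min_qual)
}

#' Filter variants on predicted impact
#'
#' Keeps records carrying at least one annotation whose impact level is in
#' `impacts` (record-level any-match, the analogue of line-level
#' `grep -E 'HIGH|MODERATE'` on an annotated VCF).
#'
#' @param vs a `variant_set`.
#' @param impacts impact levels to keep (default HIGH and MODERATE).
#' @return the filtered `variant_set`.
#' @export
filter_impact <- function(vs, impacts = c("HIGH", "MODERATE")) {
  if (!all(impacts %in% impact_levels))
    stop_arg("impacts must be among ", paste(impact_levels, collapse = ", "))
  keep <- vapply(vs$ann, function(a) any(a$impact %in% impacts), logical(1))
  subset_records(vs, keep)
}

#' Keep variants with at least one homozygous-ALT sample
#'
#' The `1/1:` gate of allele mining: a variant is informative only if some
#' line actually carries the alternative allele in homozygous state.
#'
#' @param vs a `variant_set`.
#' @return the filtered `variant_set`.
#' @export
filter_hom_alt <- function(vs) {
  keep <- rowSums(vs$gt == 2L, na.rm = TRUE) >= 1
  subset_records(vs, keep)
}

#' Genes affected by consequential variants
#'
#' Union of gene ids over annotations with impact in `impacts`, deduplicated
#' and sorted.
#'
#' @param vs a `variant_set`.
#' @param impacts impact levels counted as consequential.
#' @return character vector of gene ids.
#' @export
genes_affected <- function(vs, impacts = c("HIGH", "MODERATE")) {
  ids <- unlist(lapply(vs$ann, function(a) a$gene_id[a$impact %in% impacts]),
                use.names = FALSE)
  sort(unique(as.character(ids)))
}

#' Subset variants to a genomic interval
#'
#' @param vs a `variant_set`.
#' @param chrom chromosome id.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return the `variant_set` restricted to `chrom:start-end`.
#' @export
subset_interval <- function(vs, chrom, start, end) {
  if (start > end) stop_arg("start must be <= end")
  keep <- vs$variants$chrom == chrom & vs$variants$pos >= start &
    vs$variants$pos <= end
  subset_records(vs, keep)
}

#' Genotype-class counts per record
#'
#' @param vs a `variant_set`.
#' @return integer matrix (records x 4) with columns `n_hom_alt`, `n_het`,
#'   `n_hom_ref`, `n_missing`; each row sums to the sample count.
#' @export
count_genotypes <- function(vs) {
  cbind(n_hom_alt = rowSums(vs$gt == 2L, na.rm = TRUE),
        n_het = rowSums(vs$gt == 1L, na.rm = TRUE),
        n_hom_ref = rowSums(vs$gt == 0L, na.rm = TRUE),
        n_missing = rowSums(is.na(vs$gt)))
}

#' Count distinct marker haplotypes
#'
#' Groups lines by their complete marker vector. Lines with any missing call
#' are not grouped (a missing call could hide either allele); they are
#' reported separately as unassigned.
#'
#' @param marker_matrix lines x markers matrix (character or numeric calls;
#'   `NA` = missing), rownames = line ids.
#' @return list with `n_haplotypes`, `assignment` (named integer haplotype
#'   index per assigned line), `groups` (list of line ids per haplotype) and
#'   `unassigned` (line ids with missing calls).
#' @export
count_haplotypes <- function(marker_matrix) {
  if (is.null(dim(marker_matrix)) || nrow(marker_matrix) == 0)
    stop_arg("marker_matrix must be a nonempty matrix")
  ids <- rownames(marker_matrix) %||% as.character(seq_len(nrow(marker_matrix)))
  complete <- !apply(is.na(marker_matrix), 1, any)
  key <- apply(marker_matrix[complete, , drop = FALSE], 1, paste,
               collapse = "\r")
  fac <- factor(key, levels = unique(key))
  groups <- split(ids[complete], fac)
  names(groups) <- paste0("H", seq_along(groups))
  assignment <- stats::setNames(as.integer(fac), ids[complete])
  list(n_haplotypes = nlevels(fac), assignment = assignment,
       groups = groups, unassigned = ids[!complete])
}
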